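# Minimal dense neural-network engine: parameter containers, forward passes
# with caches, hand-derived backward passes, and an Adam optimizer. Written
# batch-first: activations are (batch x width) matrices so all heavy work is
# BLAS matrix products. Gradient correctness is established against central
# finite differences in the test suite.

glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

# --- generic nested-list parameter utilities -------------------------------

param_map <- function(f, a, b = NULL) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (k in seq_along(a))
      out[[k]] <- param_map(f, a[[k]], if (is.null(b)) NULL else b[[k]])
    out
  } else if (is.null(b)) f(a) else f(a, b)
}

zeros_like <- function(p) param_map(function(x) x * 0, p)

params_finite <- function(p) {
  ok <- TRUE
  param_map(function(x) { if (!all(is.finite(x))) ok <<- FALSE; x }, p)
  ok
}

# Flatten to / restore from a single numeric vector (used by the
# finite-difference gradient checks).
params_flatten <- function(p) {
  out <- numeric(0)
  param_map(function(x) { out <<- c(out, as.numeric(x)); x }, p)
  out
}

params_unflatten <- function(p, v) {
  i <- 0L
  param_map(function(x) {
    n <- length(x)
    x[] <- v[(i + 1L):(i + n)]
    i <<- i + n
    x
  }, p)
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L,
       lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  state$m <- param_map(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
  state$v <- param_map(function(v, g) b2 * v + (1 - b2) * g * g,
                       state$v, grads)
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  upd <- param_map(function(m, v) state$lr * (m / c1) /
                     (sqrt(v / c2) + state$eps), state$m, state$v)
  params <- param_map(function(p, u) p - u, params, upd)
  list(state = state, params = params)
}

# --- elementary layers -----------------------------------------------------

linear_fwd <- function(X, W, b) sweep(X %*% W, 2, b, "+")

# returns grads (dW, db) and upstream dX
linear_bwd <- function(X, W, dY) {
  list(dW = crossprod(X, dY), db = colSums(dY), dX = dY %*% t(W))
}

relu_fwd <- function(X) X * (X > 0)
relu_bwd <- function(X, dY) dY * (X > 0)

# row-wise softmax of a matrix
softmax_rows <- function(X) {
  Z <- exp(X - apply(X, 1, max))
  Z / rowSums(Z)
}

# --- MLP encoder (74 -> hidden -> hidden -> d), two hidden ReLU layers ----

mlp_encoder_init <- function(p_in, hidden, d) {
  list(W1 = glorot(p_in, hidden), b1 = numeric(hidden),
       W2 = glorot(hidden, hidden), b2 = numeric(hidden),
       W3 = glorot(hidden, d), b3 = numeric(d))
}

mlp_encoder_fwd <- function(params, X) {
  A1 <- linear_fwd(X, params$W1, params$b1); H1 <- relu_fwd(A1)
  A2 <- linear_fwd(H1, params$W2, params$b2); H2 <- relu_fwd(A2)
  Z <- linear_fwd(H2, params$W3, params$b3)
  list(Z = Z, cache = list(X = X, A1 = A1, H1 = H1, A2 = A2, H2 = H2))
}

mlp_encoder_bwd <- function(params, cache, dZ) {
  l3 <- linear_bwd(cache$H2, params$W3, dZ)
  dA2 <- relu_bwd(cache$A2, l3$dX)
  l2 <- linear_bwd(cache$H1, params$W2, dA2)
  dA1 <- relu_bwd(cache$A1, l2$dX)
  l1 <- linear_bwd(cache$X, params$W1, dA1)
  list(W1 = l1$dW, b1 = l1$db, W2 = l2$dW, b2 = l2$db,
       W3 = l3$dW, b3 = l3$db)
}

# --- attention encoder -----------------------------------------------------
# The 74-d fragment vector is linearly projected into T slot tokens; the
# slots exchange information through multi-head self-attention with a
# residual connection, are mean-pooled, and projected to the code dimension.

attn_encoder_init <- function(p_in, hidden, d, slots, heads) {
  stopifnot(hidden %% heads == 0)
  list(
    Wslot = lapply(seq_len(slots), function(t) glorot(p_in, hidden)),
    bslot = lapply(seq_len(slots), function(t) numeric(hidden)),
    Wq = glorot(hidden, hidden), bq = numeric(hidden),
    Wk = glorot(hidden, hidden), bk = numeric(hidden),
    Wv = glorot(hidden, hidden), bv = numeric(hidden),
    Wo = glorot(hidden, hidden), bo = numeric(hidden),
    Wout = glorot(hidden, d), bout = numeric(d))
}

attn_encoder_fwd <- function(params, X, slots, heads) {
  Tn <- slots; h <- ncol(params$Wq); dh <- h / heads; m <- nrow(X)
  S <- lapply(seq_len(Tn), function(t)
    linear_fwd(X, params$Wslot[[t]], params$bslot[[t]]))
  Q <- lapply(S, function(s) linear_fwd(s, params$Wq, params$bq))
  K <- lapply(S, function(s) linear_fwd(s, params$Wk, params$bk))
  V <- lapply(S, function(s) linear_fwd(s, params$Wv, params$bv))
  idx <- lapply(seq_len(heads), function(a) ((a - 1) * dh + 1):(a * dh))
  # A[[a]][[i]]: m x Tn attention weights of query slot i over key slots
  A <- vector("list", heads)
  O <- lapply(seq_len(Tn), function(i) matrix(0, m, h))
  for (a in seq_len(heads)) {
    A[[a]] <- vector("list", Tn)
    for (i in seq_len(Tn)) {
      logits <- sapply(seq_len(Tn), function(j)
        rowSums(Q[[i]][, idx[[a]], drop = FALSE] *
                K[[j]][, idx[[a]], drop = FALSE]) / sqrt(dh))
      if (m == 1L) logits <- matrix(logits, 1L)
      Aia <- softmax_rows(logits)
      A[[a]][[i]] <- Aia
      acc <- matrix(0, m, dh)
      for (j in seq_len(Tn))
        acc <- acc + Aia[, j] * V[[j]][, idx[[a]], drop = FALSE]
      O[[i]][, idx[[a]]] <- acc
    }
  }
  Cn <- lapply(seq_len(Tn), function(i) linear_fwd(O[[i]], params$Wo, params$bo))
  H <- lapply(seq_len(Tn), function(i) S[[i]] + Cn[[i]])
  P <- Reduce(`+`, H) / Tn
  Z <- linear_fwd(P, params$Wout, params$bout)
  list(Z = Z, cache = list(X = X, S = S, Q = Q, K = K, V = V, A = A,
                           O = O, P = P, idx = idx, slots = Tn,
                           heads = heads, dh = dh))
}

attn_encoder_bwd <- function(params, cache, dZ) {
  Tn <- cache$slots; heads <- cache$heads; dh <- cache$dh
  idx <- cache$idx; m <- nrow(dZ); h <- ncol(params$Wq)
  g <- zeros_like(params)

  lout <- linear_bwd(cache$P, params$Wout, dZ)
  g$Wout <- lout$dW; g$bout <- lout$db
  dP <- lout$dX
  dS <- lapply(seq_len(Tn), function(i) dP / Tn)   # residual branch
  dO <- vector("list", Tn)
  for (i in seq_len(Tn)) {
    lo <- linear_bwd(cache$O[[i]], params$Wo, dP / Tn)
    g$Wo <- g$Wo + lo$dW; g$bo <- g$bo + lo$db
    dO[[i]] <- lo$dX
  }
  dQ <- lapply(seq_len(Tn), function(i) matrix(0, m, h))
  dK <- dQ; dV <- dQ
  for (a in seq_len(heads)) {
    for (i in seq_len(Tn)) {
      Aia <- cache$A[[a]][[i]]
      dOia <- dO[[i]][, idx[[a]], drop = FALSE]
      dA <- sapply(seq_len(Tn), function(j)
        rowSums(dOia * cache$V[[j]][, idx[[a]], drop = FALSE]))
      if (m == 1L) dA <- matrix(dA, 1L)
      for (j in seq_len(Tn))
        dV[[j]][, idx[[a]]] <- dV[[j]][, idx[[a]], drop = FALSE] +
          Aia[, j] * dOia
      # softmax backward over the key axis
      dlog <- Aia * (dA - rowSums(Aia * dA))
      for (j in seq_len(Tn)) {
        dQ[[i]][, idx[[a]]] <- dQ[[i]][, idx[[a]], drop = FALSE] +
          dlog[, j] * cache$K[[j]][, idx[[a]], drop = FALSE] / sqrt(dh)
        dK[[j]][, idx[[a]]] <- dK[[j]][, idx[[a]], drop = FALSE] +
          dlog[, j] * cache$Q[[i]][, idx[[a]], drop = FALSE] / sqrt(dh)
      }
    }
  }
  for (i in seq_len(Tn)) {
    lq <- linear_bwd(cache$S[[i]], params$Wq, dQ[[i]])
    lk <- linear_bwd(cache$S[[i]], params$Wk, dK[[i]])
    lv <- linear_bwd(cache$S[[i]], params$Wv, dV[[i]])
    g$Wq <- g$Wq + lq$dW; g$bq <- g$bq + lq$db
    g$Wk <- g$Wk + lk$dW; g$bk <- g$bk + lk$db
    g$Wv <- g$Wv + lv$dW; g$bv <- g$bv + lv$db
    dS[[i]] <- dS[[i]] + lq$dX + lk$dX + lv$dX
    ls <- linear_bwd(cache$X, params$Wslot[[i]], dS[[i]])
    g$Wslot[[i]] <- ls$dW; g$bslot[[i]] <- ls$db
  }
  g
}

# --- decoder (d -> hidden -> 74), one hidden ReLU layer x2 -----------------

decoder_init <- function(d, hidden, p_out) {
  list(W1 = glorot(d, hidden), b1 = numeric(hidden),
       W2 = glorot(hidden, p_out), b2 = numeric(p_out))
}

decoder_fwd <- function(params, Z) {
  A1 <- linear_fwd(Z, params$W1, params$b1); H1 <- relu_fwd(A1)
  Y <- linear_fwd(H1, params$W2, params$b2)
  list(Y = Y, cache = list(Z = Z, A1 = A1, H1 = H1))
}

decoder_bwd <- function(params, cache, dY) {
  l2 <- linear_bwd(cache$H1, params$W2, dY)
  dA1 <- relu_bwd(cache$A1, l2$dX)
  l1 <- linear_bwd(cache$Z, params$W1, dA1)
  list(grads = list(W1 = l1$dW, b1 = l1$db, W2 = l2$dW, b2 = l2$db),
       dZ = l1$dX)
}
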