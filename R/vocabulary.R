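#' Training configuration for the vector-quantized autoencoder
#'
#' @param K Vocabulary size (number of codebook entries), default 1024.
#' @param d Code dimension, default 64.
#' @param beta Commitment-loss weight, default 0.25.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param seed Integer seed (mandatory); all stochasticity (initialization,
#'   shuffling) flows from it.
#' @param encoder_kind `"attention"` (slot-projection multi-head
#'   self-attention encoder) or `"mlp"` (two hidden layers).
#' @param recon_loss `"mse"` or `"kl"` (softmax-distribution KL divergence).
#' @param heads Attention heads (attention encoder only).
#' @param slots Number of slot tokens the input is projected into
#'   (attention encoder only; default 3, one per feature block).
#' @param hidden Hidden width of encoder/decoder layers.
#' @param standardize Whether to z-score features before training (the
#'   parameters are stored with the vocabulary and re-applied at
#'   tokenization).
#' @return A list of class `scg_vq_config`.
#' @export
vq_config <- function(K = 1024L, d = 64L, beta = 0.25, lr = 1e-3,
                      batch_size = 256L, epochs = 30L, seed,
                      encoder_kind = c("attention", "mlp"),
                      recon_loss = c("mse", "kl"),
                      heads = 4L, slots = 3L, hidden = 32L,
                      standardize = TRUE) {
  if (missing(seed) || is.null(seed))
    scg_error("a seed is mandatory in the training config", "scg_config_error")
  encoder_kind <- match.arg(encoder_kind)
  recon_loss <- match.arg(recon_loss)
  if (beta < 0) scg_error("beta must be non-negative", "scg_config_error")
  if (K < 2) scg_error("K must be at least 2", "scg_config_error")
  num_pos <- c(K = K, d = d, lr = lr, batch_size = batch_size,
               epochs = epochs, heads = heads, slots = slots, hidden = hidden)
  if (any(num_pos <= 0))
    scg_error("all numeric config fields must be positive", "scg_config_error")
  structure(list(K = as.integer(K), d = as.integer(d), beta = beta, lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 encoder_kind = encoder_kind, recon_loss = recon_loss,
                 heads = as.integer(heads), slots = as.integer(slots),
                 hidden = as.integer(hidden), standardize = standardize),
            class = "scg_vq_config")
}

#' Nearest-codebook quantization
#'
#' Maps a latent vector to the nearest code vector in Euclidean distance;
#' the code's row index is the discrete token. Ties are broken toward the
#' lowest index for determinism.
#'
#' @param z_e Latent d-vector (encoder output).
#' @param codebook K x d codebook matrix, or an `scg_vocab`.
#' @return A list with `z_e`, `token` (0-based), `z_q` (the selected code
#'   vector) and `distance` (Euclidean).
#' @export
quantize <- function(z_e, codebook) {
  E <- if (inherits(codebook, "scg_vocab")) codebook$codebook else codebook
  if (is.null(dim(E)) || nrow(E) == 0L)
    scg_error("empty codebook", "scg_empty_input_error")
  if (length(z_e) != ncol(E))
    scg_error("z_e dimension does not match codebook", "scg_shape_error")
  d2 <- rowSums(sweep(E, 2, z_e, "-")^2)
  k <- which.min(d2)                      # which.min: first (lowest-index) tie
  list(z_e = z_e, token = k - 1L, z_q = E[k, ], distance = sqrt(d2[k]))
}

# Batch quantization: rows of Z against codebook E. Returns 0-based tokens
# and the selected code rows.
quantize_batch <- function(Z, E) {
  D <- sweep(-2 * Z %*% t(E), 2, rowSums(E * E), "+")
  tokens <- max.col(-D, ties.method = "first")
  list(tokens = tokens - 1L, Zq = E[tokens, , drop = FALSE])
}

#' Straight-through estimator
#'
#' Forward value is the quantized code `z_q`; on the backward pass the
#' quantization step is treated as the identity, so the gradient arriving
#' at the output is passed to the encoder output `z_e` unchanged (see
#' [ste_backward()]).
#'
#' @param z_e Encoder output (vector or batch matrix).
#' @param z_q Quantized counterpart, same shape.
#' @return `z_q`, the decoder input.
#' @export
straight_through <- function(z_e, z_q) {
  if (length(z_e) != length(z_q))
    scg_error("z_e and z_q shapes differ", "scg_shape_error")
  z_q
}

#' @rdname straight_through
#' @param grad_out Gradient with respect to the straight-through output.
#' @return `ste_backward()` returns the gradient with respect to `z_e`,
#'   which is `grad_out` itself (identity Jacobian).
#' @export
ste_backward <- function(grad_out) grad_out

# KL(p || q) between row-wise softmax views of X (input) and Y (logits of
# the reconstruction); mean over rows. Returns loss and d/dY.
kl_recon <- function(X, Y) {
  if (is.null(dim(X))) { X <- matrix(X, 1L); Y <- matrix(Y, 1L) }
  m <- nrow(X)
  P <- softmax_rows(X); Q <- softmax_rows(Y)
  loss <- sum(P * (log(P + 1e-30) - log(Q + 1e-30))) / m
  list(loss = loss, dY = (Q - P) / m)
}

mse_recon <- function(X, Y) {
  if (is.null(dim(X))) { X <- matrix(X, 1L); Y <- matrix(Y, 1L) }
  list(loss = mean((Y - X)^2), dY = 2 * (Y - X) / length(X))
}

#' Decompose the vector-quantization training loss
#'
#' Total loss = reconstruction + codebook + beta * commitment. The
#' reconstruction term compares input and reconstruction (KL divergence
#' between their softmax distribution views, or mean squared error); the
#' codebook term is the squared Euclidean distance between the (detached)
#' encoder output and its code vector, pulling only the codebook; the
#' commitment term is the same distance pulling only the encoder. With
#' batch inputs, squared distances are summed over the code dimension and
#' averaged over the batch.
#'
#' @param x Input feature vector or batch matrix (standardized scale).
#' @param x_hat Reconstruction (same shape; logits under the KL form).
#' @param z_e Encoder output (vector or batch matrix).
#' @param z_q Quantized counterpart.
#' @param beta Commitment weight (non-negative).
#' @param recon_loss `"mse"` or `"kl"`.
#' @return List with `recons`, `codebook`, `commit`, `beta`, `total`.
#' @export
vq_losses <- function(x, x_hat, z_e, z_q, beta = 0.25,
                      recon_loss = c("mse", "kl")) {
  recon_loss <- match.arg(recon_loss)
  if (beta < 0) scg_error("beta must be non-negative", "scg_config_error")
  recons <- if (recon_loss == "kl") kl_recon(x, x_hat)$loss
            else mse_recon(x, x_hat)$loss
  Ze <- if (is.null(dim(z_e))) matrix(z_e, 1L) else z_e
  Zq <- if (is.null(dim(z_q))) matrix(z_q, 1L) else z_q
  qerr <- sum((Ze - Zq)^2) / nrow(Ze)
  list(recons = recons, codebook = qerr, commit = qerr, beta = beta,
       total = recons + qerr + beta * qerr)
}

# --- model assembly --------------------------------------------------------

init_vq_params <- function(config, p_in) {
  enc <- if (config$encoder_kind == "attention")
    attn_encoder_init(p_in, config$hidden, config$d, config$slots,
                      config$heads)
  else mlp_encoder_init(p_in, max(config$hidden, 64L), config$d)
  dec <- decoder_init(config$d, max(config$hidden, 64L), p_in)
  list(enc = enc, dec = dec)
}

encoder_fwd <- function(params, X, config) {
  if (config$encoder_kind == "attention")
    attn_encoder_fwd(params, X, config$slots, config$heads)
  else mlp_encoder_fwd(params, X)
}

encoder_bwd <- function(params, cache, dZ, config) {
  if (config$encoder_kind == "attention") attn_encoder_bwd(params, cache, dZ)
  else mlp_encoder_bwd(params, cache, dZ)
}

# One forward/backward pass over a standardized batch. `terms` selects
# which loss terms contribute gradients, so the stop-gradient contracts
# (codebook term -> codebook only; commitment term -> encoder only) are
# directly inspectable.
vq_forward_backward <- function(params, E, X, config,
                                terms = c("recons", "codebook", "commit")) {
  m <- nrow(X)
  eo <- encoder_fwd(params$enc, X, config)
  Z <- eo$Z
  q <- quantize_batch(Z, E)
  Zdec <- straight_through(Z, q$Zq)
  do <- decoder_fwd(params$dec, Zdec)
  rec <- if (config$recon_loss == "kl") kl_recon(X, do$Y)
         else mse_recon(X, do$Y)
  qerr <- sum((Z - q$Zq)^2) / m
  losses <- list(recons = rec$loss, codebook = qerr, commit = qerr,
                 beta = config$beta,
                 total = rec$loss + qerr + config$beta * qerr)

  dZ <- matrix(0, m, config$d)
  g_dec <- zeros_like(params$dec)
  g_E <- E * 0
  if ("recons" %in% terms) {
    db <- decoder_bwd(params$dec, do$cache, rec$dY)
    g_dec <- db$grads
    dZ <- dZ + ste_backward(db$dZ)       # straight-through to the encoder
  }
  if ("codebook" %in% terms) {
    used <- sort(unique(q$tokens))
    cnt <- tabulate(q$tokens + 1L, nbins = nrow(E))
    Zsum <- rowsum(Z, group = q$tokens, reorder = TRUE)
    g_E[used + 1L, ] <- 2 * (cnt[used + 1L] * E[used + 1L, , drop = FALSE] -
                               Zsum) / m
  }
  if ("commit" %in% terms) dZ <- dZ + config$beta * 2 * (Z - q$Zq) / m
  g_enc <- encoder_bwd(params$enc, eo$cache, dZ, config)
  list(losses = losses, tokens = q$tokens,
       grads = list(enc = g_enc, dec = g_dec, E = g_E))
}

# Greedy k-means++ seeding: each new center is chosen among several
# D^2-weighted candidates as the one minimizing the resulting potential
# (the variant scikit-learn uses); far more robust than plain D^2 sampling
# against double-seeding one cluster.
kmeanspp_centers <- function(Z, K) {
  m <- nrow(Z)
  n_cand <- 2L + as.integer(floor(log(K)))
  centers <- matrix(0, K, ncol(Z))
  centers[1, ] <- Z[sample.int(m, 1L), ]
  d2 <- rowSums(sweep(Z, 2, centers[1, ], "-")^2)
  for (k in seq_len(K - 1L)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / m, m)
    cand <- sample.int(m, n_cand, prob = p, replace = TRUE)
    best <- NULL; best_pot <- Inf
    for (ci in cand) {
      nd2 <- pmin(d2, rowSums(sweep(Z, 2, Z[ci, ], "-")^2))
      if (sum(nd2) < best_pot) { best_pot <- sum(nd2); best <- ci; bd2 <- nd2 }
    }
    centers[k + 1L, ] <- Z[best, ]
    d2 <- bd2
  }
  centers
}

#' Train the vector-quantized autoencoder vocabulary
#'
#' Jointly trains encoder, decoder and codebook by minibatch Adam on the
#' three-term loss (reconstruction + codebook + beta * commitment), with
#' straight-through gradients across the quantization step. The codebook is
#' initialized by k-means++ seeding on encoder outputs of an initial sample
#' to mitigate dead codes. Fully reproducible given the config seed.
#'
#' @param features m x 74 fragment feature matrix (raw scale).
#' @param config An [vq_config()] object.
#' @return An object of class `scg_vocab`: codebook (K x d), encoder and
#'   decoder parameters, standardization, config, per-epoch training log
#'   (losses and codebook utilization) and a manifest hash.
#' @export
train_vqvae <- function(features, config) {
  X <- as.matrix(features)
  m <- nrow(X); p <- ncol(X)
  if (m < 2L) scg_error("need at least 2 feature rows", "scg_empty_input_error")
  std <- if (config$standardize) fit_standardization(X)
         else list(center = numeric(p), scale = rep(1, p))
  Xs <- apply_standardization(X, std)

  with_seed(derive_seed(config$seed, "vqvae"), {
    params <- init_vq_params(config, p)
    init_idx <- sample.int(m, min(m, max(4L * config$K, 512L)))
    Z0 <- encoder_fwd(params$enc, Xs[init_idx, , drop = FALSE], config)$Z
    E <- if (nrow(Z0) > config$K) {
      km0 <- suppressWarnings(
        stats::kmeans(Z0, centers = kmeanspp_centers(Z0, config$K),
                      iter.max = 20L))
      unname(km0$centers)
    } else Z0[sample.int(nrow(Z0), config$K, replace = TRUE), ] +
        matrix(stats::rnorm(config$K * config$d, sd = 0.01),
               config$K, config$d)

    all_p <- list(enc = params$enc, dec = params$dec, E = E)
    opt <- adam_init(all_p, lr = config$lr)
    log <- vector("list", config$epochs)
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(m)
      nb <- ceiling(m / config$batch_size)
      acc <- c(recons = 0, codebook = 0, commit = 0, total = 0)
      tokens_seen <- integer(0)
      for (b in seq_len(nb)) {
        idx <- perm[((b - 1L) * config$batch_size + 1L):
                      min(b * config$batch_size, m)]
        fb <- vq_forward_backward(list(enc = all_p$enc, dec = all_p$dec),
                                  all_p$E, Xs[idx, , drop = FALSE], config)
        if (!is.finite(fb$losses$total))
          scg_error(sprintf(
            "non-finite loss at epoch %d, batch %d: recons=%g codebook=%g",
            ep, b, fb$losses$recons, fb$losses$codebook),
            "scg_numeric_error")
        st <- adam_step(opt, all_p, fb$grads)
        opt <- st$state; all_p <- st$params
        acc <- acc + c(fb$losses$recons, fb$losses$codebook,
                       fb$losses$commit, fb$losses$total)
        tokens_seen <- union(tokens_seen, unique(fb$tokens))
      }
      log[[ep]] <- data.frame(
        epoch = ep, recons = acc[1] / nb, codebook = acc[2] / nb,
        commit = acc[3] / nb, total = acc[4] / nb,
        utilization = length(tokens_seen) / config$K)
    }
    vocab <- structure(list(
      kind = "vqvae", codebook = all_p$E, encoder = all_p$enc,
      decoder = all_p$dec, config = config, standardization = std,
      log = do.call(rbind, log)), class = "scg_vocab")
    vocab$hash <- vocab_hash(vocab)
    vocab
  })
}

#' Train a k-means baseline vocabulary
#'
#' Clusters standardized 74-d fragment features directly (no encoder); the
#' K centroids act as the codebook and tokenization assigns the nearest
#' centroid with the same lowest-index tie-break as [quantize()].
#'
#' @param features m x 74 feature matrix.
#' @param K Number of centroids.
#' @param seed Integer seed.
#' @param standardize Whether to z-score features first.
#' @return An `scg_vocab` of kind `"kmeans"` (code dimension 74).
#' @export
train_kmeans_vocab <- function(features, K, seed, standardize = TRUE) {
  X <- as.matrix(features)
  m <- nrow(X); p <- ncol(X)
  if (m < K)
    scg_error(sprintf("need at least K=%d rows, got %d", K, m),
              "scg_empty_input_error")
  std <- if (standardize) fit_standardization(X)
         else list(center = numeric(p), scale = rep(1, p))
  Xs <- apply_standardization(X, std)
  centers <- with_seed(derive_seed(seed, "kmeans-vocab"), {
    if (K == m) Xs
    else {
      # best of several Lloyd runs from greedy k-means++ seedings
      best <- NULL; best_ss <- Inf
      for (r in 1:5) {
        km <- suppressWarnings(
          stats::kmeans(Xs, centers = kmeanspp_centers(Xs, K),
                        iter.max = 100L))
        if (km$tot.withinss < best_ss) { best_ss <- km$tot.withinss; best <- km }
      }
      best$centers
    }
  })
  dimnames(centers) <- NULL
  cfg <- vq_config(K = K, d = p, seed = seed, standardize = standardize)
  vocab <- structure(list(
    kind = "kmeans", codebook = centers, encoder = NULL, decoder = NULL,
    config = cfg, standardization = std, log = NULL), class = "scg_vocab")
  vocab$hash <- vocab_hash(vocab)
  vocab
}

#' @export
print.scg_vocab <- function(x, ...) {
  cat(sprintf("<scg_vocab %s: K=%d, d=%d, hash=%s>\n",
              x$kind, nrow(x$codebook), ncol(x$codebook), x$hash))
  invisible(x)
}

#' Encode raw fragment features into the latent space
#'
#' Applies the vocabulary's stored standardization, then its encoder
#' (identity for a k-means vocabulary).
#'
#' @param vocab An `scg_vocab`.
#' @param x A 74-vector or an m x 74 matrix of raw features.
#' @return Latent matrix (rows = fragments) of width `d`.
#' @export
vq_encode <- function(vocab, x) {
  X <- if (is.null(dim(x))) matrix(x, 1L) else as.matrix(x)
  if (ncol(X) != length(vocab$standardization$center))
    scg_error("feature dimension does not match vocabulary", "scg_shape_error")
  Xs <- apply_standardization(X, vocab$standardization)
  if (vocab$kind == "kmeans") return(Xs)
  encoder_fwd(vocab$encoder, Xs, vocab$config)$Z
}

#' Tokenize raw fragment features
#'
#' @param vocab An `scg_vocab`.
#' @param x A 74-vector or m x 74 matrix of raw features.
#' @return Integer vector of 0-based tokens.
#' @export
tokenize_features <- function(vocab, x) {
  Z <- vq_encode(vocab, x)
  quantize_batch(Z, vocab$codebook)$tokens
}

#' Codebook utilization
#'
#' Fraction of codebook entries assigned at least once; low values signal
#' codebook collapse.
#'
#' @param tokens Integer vector of 0-based token ids.
#' @param K Vocabulary size.
#' @return Fraction in [0, 1].
#' @export
codebook_utilization <- function(tokens, K) {
  if (length(tokens) && (min(tokens) < 0L || max(tokens) >= K))
    scg_error("token id out of range [0, K)", "scg_range_error")
  length(unique(tokens)) / K
}

# Manifest hash over everything that determines tokenization.
vocab_hash <- function(vocab) {
  object_md5(list(kind = vocab$kind, K = nrow(vocab$codebook),
                  d = ncol(vocab$codebook),
                  codebook = as.numeric(vocab$codebook),
                  center = vocab$standardization$center,
                  scale = vocab$standardization$scale,
                  encoder = if (is.null(vocab$encoder)) NULL
                            else params_flatten(vocab$encoder),
                  encoder_kind = vocab$config$encoder_kind,
                  seed = vocab$config$seed))
}

# serialize nested parameter lists (arrays) to JSON-safe structures
serialize_params <- function(p) {
  if (is.list(p)) lapply(p, serialize_params)
  else list(.dim = if (is.null(dim(p))) length(p) else dim(p),
            .data = as.numeric(p))
}

deserialize_params <- function(s) {
  if (!is.null(s$.data)) {
    v <- as.numeric(s$.data)
    if (length(s$.dim) > 1L) array(v, dim = as.integer(s$.dim)) else v
  } else lapply(s, deserialize_params)
}

#' Save / load a vocabulary artifact
#'
#' The artifact is a directory holding the codebook as TSV, encoder/decoder
#' parameters as JSON, and a JSON manifest (K, d, beta, encoder kind,
#' standardization, seed, hash).
#'
#' @param vocab An `scg_vocab`.
#' @param dir Artifact directory (created if needed).
#' @return `save_vocab()` returns `dir` invisibly; `load_vocab()` returns
#'   the restored `scg_vocab`.
#' @export
save_vocab <- function(vocab, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  # %.17g keeps doubles exact through the text round trip
  writeLines(apply(vocab$codebook, 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t")),
    file.path(dir, "codebook.tsv"))
  params <- list(encoder = if (is.null(vocab$encoder)) NULL
                           else serialize_params(vocab$encoder),
                 decoder = if (is.null(vocab$decoder)) NULL
                           else serialize_params(vocab$decoder))
  writeLines(jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             file.path(dir, "params.json"))
  manifest <- list(kind = vocab$kind, config = unclass(vocab$config),
                   standardization = vocab$standardization,
                   hash = vocab$hash)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(dir, "manifest.json"))
  if (!is.null(vocab$log))
    utils::write.table(vocab$log, file.path(dir, "training_log.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname save_vocab
#' @export
load_vocab <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  E <- as.matrix(utils::read.table(file.path(dir, "codebook.tsv"),
                                   sep = "\t", header = FALSE))
  dimnames(E) <- NULL
  pj <- jsonlite::fromJSON(file.path(dir, "params.json"),
                           simplifyVector = TRUE, simplifyDataFrame = FALSE,
                           simplifyMatrix = FALSE)
  cfg <- manifest$config
  config <- vq_config(K = cfg$K, d = cfg$d, beta = cfg$beta, lr = cfg$lr,
                      batch_size = cfg$batch_size, epochs = cfg$epochs,
                      seed = cfg$seed, encoder_kind = cfg$encoder_kind,
                      recon_loss = cfg$recon_loss, heads = cfg$heads,
                      slots = cfg$slots, hidden = cfg$hidden,
                      standardize = cfg$standardize)
  vocab <- structure(list(
    kind = manifest$kind, codebook = E,
    encoder = if (is.null(pj$encoder)) NULL else deserialize_params(pj$encoder),
    decoder = if (is.null(pj$decoder)) NULL else deserialize_params(pj$decoder),
    config = config,
    standardization = list(center = manifest$standardization$center,
                           scale = manifest$standardization$scale),
    log = NULL), class = "scg_vocab")
  vocab$hash <- vocab_hash(vocab)
  if (!identical(vocab$hash, manifest$hash))
    scg_error("vocabulary manifest hash mismatch: artifact corrupted or edited",
              "scg_version_error")
  vocab
}
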