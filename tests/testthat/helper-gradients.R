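# Finite-difference oracle for the manual backward passes. The analytic
# gradients implement the straight-through / stop-gradient computational
# graph, so they are compared against central finite differences of the
# surrogate objective that graph defines: tokens and quantization offset
# frozen at the evaluation point, detached quantities held constant.

ste_surrogate_fd_gap <- function(encoder_kind, seed = 1, n_coords = 80) {
  set.seed(seed)
  cfg <- vq_config(K = 3, d = 4, seed = seed, encoder_kind = encoder_kind,
                   hidden = 8, heads = 2, slots = 2, recon_loss = "mse")
  p_in <- 6
  X <- matrix(rnorm(5 * p_in), 5, p_in)
  params <- scglang:::init_vq_params(cfg, p_in)
  E <- matrix(rnorm(3 * 4), 3, 4)
  all_p <- list(enc = params$enc, dec = params$dec, E = E)
  fb <- scglang:::vq_forward_backward(params, E, X, cfg)
  gflat <- scglang:::params_flatten(fb$grads)
  v0 <- scglang:::params_flatten(all_p)
  Z0 <- scglang:::encoder_fwd(all_p$enc, X, cfg)$Z
  q0 <- scglang:::quantize_batch(Z0, E)
  C0 <- q0$Zq - Z0
  m <- nrow(X)
  f <- function(v) {
    p <- scglang:::params_unflatten(all_p, v)
    Z <- scglang:::encoder_fwd(p$enc, X, cfg)$Z
    Y <- scglang:::decoder_fwd(p$dec, Z + C0)$Y
    recons <- mean((Y - X)^2)
    codebook <- sum((Z0 - p$E[q0$tokens + 1L, , drop = FALSE])^2) / m
    commit <- sum((Z - q0$Zq)^2) / m
    recons + codebook + cfg$beta * commit
  }
  eps <- 1e-5
  idx <- sort(sample(length(v0), min(n_coords, length(v0))))
  num <- vapply(idx, function(i) {
    vp <- v0; vp[i] <- vp[i] + eps
    vm <- v0; vm[i] <- vm[i] - eps
    (f(vp) - f(vm)) / (2 * eps)
  }, numeric(1))
  max(abs(num - gflat[idx]))
}
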