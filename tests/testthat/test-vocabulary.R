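test_that("quantization selects the nearest code with lowest-index ties", {
  E <- rbind(c(0, 0), c(1, 1))
  q <- quantize(c(0.1, 0.1), E)
  expect_equal(q$token, 0L)
  expect_equal(q$z_q, c(0, 0))
  expect_equal(q$distance, sqrt(0.02))

  q <- quantize(c(0.5, 0.5), E)   # exactly equidistant
  expect_equal(q$token, 0L)

  expect_error(quantize(c(1, 2), matrix(numeric(0), 0, 2)),
               class = "scg_empty_input_error")
  expect_error(quantize(c(1, 2, 3), E), class = "scg_shape_error")
})

test_that("quantization agrees with the exhaustive-scan oracle", {
  set.seed(51)
  for (rep in 1:100) {
    K <- sample(2:16, 1); d <- sample(2:8, 1)
    E <- matrix(rnorm(K * d), K, d)
    z <- rnorm(d)
    oracle <- which.min(apply(E, 1, function(e) sqrt(sum((z - e)^2)))) - 1L
    expect_identical(quantize(z, E)$token, oracle)
  }
  # batch path agrees with the per-vector path
  E <- matrix(rnorm(10 * 4), 10, 4)
  Z <- matrix(rnorm(30 * 4), 30, 4)
  batch <- scglang:::quantize_batch(Z, E)$tokens
  single <- vapply(seq_len(30), function(i) quantize(Z[i, ], E)$token,
                   integer(1))
  expect_identical(batch, single)
})

test_that("loss terms decompose as reconstruction + codebook + beta * commitment", {
  # identical distributions give zero KL reconstruction
  x <- c(1, 2, 3)
  l <- vq_losses(x, x, c(0, 0), c(0, 0), beta = 0.25, recon_loss = "kl")
  expect_equal(l$recons, 0, tolerance = 1e-9)

  l <- vq_losses(x, x, c(1, 2), c(1, 2), beta = 0.25)
  expect_equal(l$codebook, 0)
  expect_equal(l$commit, 0)

  l <- vq_losses(x, x, c(0, 0), c(3, 4), beta = 0.25)
  expect_equal(l$codebook, 25)
  expect_equal(l$commit, 25)
  expect_equal(l$total - l$recons, 25 + 6.25)

  expect_error(vq_losses(x, x, c(0, 0), c(0, 0), beta = -1),
               class = "scg_config_error")

  set.seed(52)
  for (rep in 1:20) {
    m <- sample(1:6, 1); p <- 7; d <- 4
    X <- matrix(rnorm(m * p), m); Y <- matrix(rnorm(m * p), m)
    Ze <- matrix(rnorm(m * d), m); Zq <- matrix(rnorm(m * d), m)
    b <- runif(1, 0, 1)
    for (rl in c("mse", "kl")) {
      l <- vq_losses(X, Y, Ze, Zq, beta = b, recon_loss = rl)
      expect_gte(l$recons, -1e-9)
      expect_equal(l$total, l$recons + l$codebook + b * l$commit,
                   tolerance = 1e-9)
    }
  }
})

test_that("the straight-through estimator passes gradients through unchanged", {
  z_e <- c(0.3, -0.8, 1.2)
  z_q <- c(0, -1, 1)
  expect_equal(straight_through(z_e, z_q), z_q)
  expect_error(straight_through(z_e, c(1, 2)), class = "scg_shape_error")
  # identity Jacobian: d(sum(out))/d(z_e) is all ones
  expect_equal(ste_backward(rep(1, 3)), rep(1, 3))
  # random probe functions: the encoder-side gradient equals the probe
  # gradient evaluated at the forward value z_q (finite-difference oracle)
  set.seed(53)
  for (rep in 1:10) {
    a <- rnorm(3); b <- rnorm(3)
    probe <- function(v) sum(a * v + b * v^2)
    g_analytic <- ste_backward(a + 2 * b * z_q)
    eps <- 1e-6
    g_fd <- vapply(1:3, function(i) {
      vp <- z_q; vp[i] <- vp[i] + eps
      vm <- z_q; vm[i] <- vm[i] - eps
      (probe(vp) - probe(vm)) / (2 * eps)
    }, numeric(1))
    expect_equal(g_analytic, g_fd, tolerance = 1e-6)
  }
})

test_that("manual backprop matches finite differences of the STE surrogate", {
  expect_lt(ste_surrogate_fd_gap("mlp"), 1e-7)
  expect_lt(ste_surrogate_fd_gap("attention"), 1e-7)
})

test_that("stop-gradients isolate the codebook and commitment terms", {
  set.seed(54)
  cfg <- vq_config(K = 4, d = 3, seed = 1, encoder_kind = "mlp", hidden = 8)
  X <- matrix(rnorm(6 * 5), 6, 5)
  params <- scglang:::init_vq_params(cfg, 5)
  E <- matrix(rnorm(4 * 3), 4, 3)
  all_p <- list(enc = params$enc, dec = params$dec, E = E)

  fb_cb <- scglang:::vq_forward_backward(params, E, X, cfg, terms = "codebook")
  expect_true(all(scglang:::params_flatten(fb_cb$grads$enc) == 0))
  expect_true(all(scglang:::params_flatten(fb_cb$grads$dec) == 0))
  expect_true(any(fb_cb$grads$E != 0))
  # one optimizer step on the codebook term leaves the encoder bitwise intact
  st <- scglang:::adam_step(scglang:::adam_init(all_p), all_p, fb_cb$grads)
  expect_identical(st$params$enc, all_p$enc)
  expect_false(identical(st$params$E, all_p$E))

  fb_cm <- scglang:::vq_forward_backward(params, E, X, cfg, terms = "commit")
  expect_true(all(fb_cm$grads$E == 0))
  expect_true(any(scglang:::params_flatten(fb_cm$grads$enc) != 0))
  st2 <- scglang:::adam_step(scglang:::adam_init(all_p), all_p, fb_cm$grads)
  expect_identical(st2$params$E, all_p$E)

  # reconstruction gradients reach decoder and (via STE) encoder, not codebook
  fb_rc <- scglang:::vq_forward_backward(params, E, X, cfg, terms = "recons")
  expect_true(all(fb_rc$grads$E == 0))
  expect_true(any(scglang:::params_flatten(fb_rc$grads$dec) != 0))
  expect_true(any(scglang:::params_flatten(fb_rc$grads$enc) != 0))
})

test_that("training reduces the loss and is reproducible", {
  mix <- gen_fragment_mixture(8, 600, 10, 1, seed = 55)
  cfg <- vq_config(K = 8, d = 16, seed = 55, epochs = 8, hidden = 16,
                   batch_size = 128)
  v1 <- train_vqvae(mix$X, cfg)
  expect_lte(v1$log$total[nrow(v1$log)], v1$log$total[1])
  v2 <- train_vqvae(mix$X, cfg)
  expect_identical(v1$codebook, v2$codebook)
  # recovery of the generating clusters on a small, well-separated mixture
  ari <- mclust::adjustedRandIndex(tokenize_features(v1, mix$X), mix$labels)
  expect_gte(ari, 0.9)
})

test_that("encoder variants share the interface and are deterministic", {
  mix <- gen_fragment_mixture(4, 80, 10, 1, seed = 56)
  for (kind in c("attention", "mlp")) {
    cfg <- vq_config(K = 4, d = 8, seed = 56, epochs = 2, hidden = 8,
                     encoder_kind = kind, batch_size = 40)
    v <- train_vqvae(mix$X, cfg)
    Z <- vq_encode(v, mix$X[1:5, ])
    expect_equal(dim(Z), c(5L, 8L))
    expect_identical(Z, vq_encode(v, mix$X[1:5, ]))
    expect_error(vq_encode(v, mix$X[1, 1:10]), class = "scg_shape_error")
  }
})

test_that("codebook utilization is the fraction of codes in use", {
  expect_equal(codebook_utilization(0:7, 8), 1)
  expect_equal(codebook_utilization(rep(3L, 50), 8), 1 / 8)
  expect_equal(codebook_utilization(c(0L, 0L, 2L), 4), 0.5)
  expect_error(codebook_utilization(c(0L, 4L), 4), class = "scg_range_error")
  expect_error(codebook_utilization(-1L, 4), class = "scg_range_error")
})

test_that("k-means vocabularies recover cloud centroids", {
  set.seed(57)
  X <- rbind(matrix(rnorm(40 * 74, mean = 0, sd = 0.1), 40),
             matrix(rnorm(40 * 74, mean = 5, sd = 0.1), 40))
  v <- train_kmeans_vocab(X, 2, seed = 57, standardize = FALSE)
  cen <- v$codebook[order(v$codebook[, 1]), ]
  expect_equal(unname(cen[1, ]), unname(colMeans(X[1:40, ])), tolerance = 0.05)
  expect_equal(unname(cen[2, ]), unname(colMeans(X[41:80, ])), tolerance = 0.05)

  # K = m: every point its own token
  Xs <- matrix(rnorm(6 * 74), 6)
  vm <- train_kmeans_vocab(Xs, 6, seed = 1)
  expect_equal(sort(tokenize_features(vm, Xs)), 0:5)

  expect_error(train_kmeans_vocab(Xs, 10, seed = 1),
               class = "scg_empty_input_error")
  v2 <- train_kmeans_vocab(X, 2, seed = 57, standardize = FALSE)
  expect_identical(v$codebook, v2$codebook)
})

test_that("vocabulary artifacts round-trip through the directory format", {
  mix <- gen_fragment_mixture(4, 120, 10, 1, seed = 58)
  v <- train_vqvae(mix$X, vq_config(K = 4, d = 8, seed = 58, epochs = 2,
                                    hidden = 8, batch_size = 60))
  dir <- tempfile()
  save_vocab(v, dir)
  v2 <- load_vocab(dir)
  expect_equal(v2$hash, v$hash)
  expect_identical(tokenize_features(v2, mix$X), tokenize_features(v, mix$X))

  km <- train_kmeans_vocab(mix$X, 4, seed = 58)
  d2 <- tempfile(); save_vocab(km, d2)
  expect_identical(tokenize_features(load_vocab(d2), mix$X),
                   tokenize_features(km, mix$X))

  # tampering with the codebook breaks the manifest hash
  cb <- readLines(file.path(dir, "codebook.tsv"))
  cb[1] <- sub("^[^\t]*", "99", cb[1])
  writeLines(cb, file.path(dir, "codebook.tsv"))
  expect_error(load_vocab(dir), class = "scg_version_error")
})

test_that("training configs validate their fields", {
  expect_error(vq_config(K = 1, seed = 1), class = "scg_config_error")
  expect_error(vq_config(beta = -0.1, seed = 1), class = "scg_config_error")
  expect_error(vq_config(K = 8), class = "scg_config_error")  # seed mandatory
  cfg <- vq_config(seed = 3)
  expect_equal(cfg$beta, 0.25)
  expect_equal(cfg$K, 1024L)
})
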