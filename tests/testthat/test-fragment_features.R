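frag_of <- function(chain) fragment_at(segment_by_ss(chain), 1L)

test_that("composition is the fraction of standard amino acids", {
  v <- composition_feature(frag_of(make_toy_chain("HHHH", aa = rep("A", 4))))
  expect_equal(unname(v[AA_ALPHABET == "A"]), 1)
  expect_equal(sum(v), 1)

  v <- composition_feature(frag_of(make_toy_chain("HHHH",
                                                  aa = c("A", "C", "D", "E"))))
  expect_equal(unname(v[c("A", "C", "D", "E")]), rep(0.25, 4))

  v <- composition_feature(frag_of(make_toy_chain("HHH", aa = c("A", "X", "A"))))
  expect_equal(unname(v["A"]), 1)

  v <- composition_feature(frag_of(make_toy_chain("HH", aa = c("X", "X"))))
  expect_equal(unname(v), numeric(20))
})

test_that("PSSM files parse row by row with format validation", {
  aa <- c("A", "C", "D")
  raw <- matrix(0L, 3, 20)
  f <- tempfile(fileext = ".pssm")
  write_pssm_file(raw, aa, f)
  expect_equal(unname(read_pssm(f)), matrix(0L, 3, 20))

  raw[1, ] <- c(2L, -1L, rep(0L, 18))
  write_pssm_file(raw, aa, f)
  expect_equal(unname(read_pssm(f)[1, ]), c(2L, -1L, rep(0L, 18)))

  expect_error(read_pssm(f, n_expected = 5), class = "scg_format_error")

  bad <- tempfile()
  writeLines(c("header", "    1 A   1  2  3"), bad)   # too few columns
  expect_error(read_pssm(bad), class = "scg_format_error")
})

test_that("sigmoid normalization matches its closed form and is monotone", {
  expect_equal(normalize_pssm(0), 0.5)
  expect_equal(normalize_pssm(2), 1 / (1 + exp(-2)))
  expect_equal(normalize_pssm(2), 0.8808, tolerance = 1e-4)
  s <- matrix(c(-10, -2, 0, 2, 10), 1)
  n <- normalize_pssm(s)
  expect_true(all(diff(as.numeric(n)) > 0))
  expect_true(all(n > 0 & n < 1))
  set.seed(12)
  r <- matrix(sample(-10:10, 40, replace = TRUE), 2)
  expect_true(all((order(r) == order(normalize_pssm(r)))))
})

test_that("HHM emission scores convert via 2^(-s/1000) with '*' as zero", {
  scores <- matrix(0L, 2, 20)
  scores[1, 1] <- 1000L
  scores[2, 2] <- NA_integer_      # written as '*'
  f <- tempfile(fileext = ".hhm")
  write_hhm_file(scores, c("A", "C"), f)
  h <- read_hhm(f)
  expect_equal(unname(h[1, 1]), 0.5)
  expect_equal(unname(h[2, 2]), 0)
  expect_equal(unname(h[1, 2]), 1)

  bad <- tempfile()
  writeLines(c("HHsearch 1.5", "HMM  A C", "A 1    10 20"), bad)
  expect_error(read_hhm(bad), class = "scg_format_error")
})

test_that("evolutionary features are column means over the fragment rows", {
  ch <- make_toy_chain("HHC")
  pssm <- matrix(rep(c(0.2, 0.4, 0.9), 20), 3, 20)
  hmm <- matrix(rep(c(0.1, 0.3, 0.7), 20), 3, 20)
  pr <- make_profile_pair(pssm, hmm)
  fr <- segment_by_ss(ch)
  # single-residue fragment: its own rows
  v <- evolutionary_feature(fragment_at(fr, 2), pr)
  expect_equal(v, c(rep(0.9, 20), rep(0.7, 20)))
  # two-residue fragment: row means per block, PSSM block first
  v <- evolutionary_feature(fragment_at(fr, 1), pr)
  expect_equal(v, c(rep(0.3, 20), rep(0.2, 20)))
  # constant rows reproduce the constant
  v <- evolutionary_feature(fragment_at(fr, 1), uniform_profiles(3))
  expect_equal(v, c(rep(0.5, 20), rep(0.25, 20)))
  # fragment outside profile range
  short <- make_profile_pair(matrix(0.5, 2, 20), matrix(0.5, 2, 20))
  expect_error(evolutionary_feature(fragment_at(fr, 2), short),
               class = "scg_range_error")
})

test_that("geometry features one-hot the SS class and average normalized fields", {
  ch <- scg_chain("A", aa = rep("A", 3), ss = rep("H", 3),
                  acc = 0, phi = -60, psi = -45)
  g <- geometry_feature(frag_of(ch))
  expect_length(g, 14L)
  expect_equal(g[1:8], as.numeric(SS_ALPHABET == "H"))
  expect_equal(g[9], 0)                 # acc
  expect_equal(g[13], -1 / 3)           # phi / 180
  expect_equal(g[14], -0.25)            # psi / 180

  sent <- scg_chain("A", aa = "A", ss = "T", kappa = 0,
                    alpha = 360, phi = 360, psi = 360)
  g <- geometry_feature(frag_of(sent))
  expect_equal(g[12:14], c(0, 0, 0))    # sentinel imputed to 0

  set.seed(31)
  for (rep in 1:10)
    expect_equal(sum(geometry_feature(frag_of(random_chain()))[1:8]), 1)
})

test_that("non-homogeneous fragments use the majority class with alphabet-order ties", {
  maj <- list(chain_id = "A", start = 0, end = 5, ss = "N",
              residues = make_toy_chain("HHEEE")$residues)
  g <- geometry_feature(maj)
  expect_equal(g[1:8], as.numeric(SS_ALPHABET == "E"))
  # tie between H (2) and E (2): H precedes E in the fixed alphabet
  tie <- list(chain_id = "A", start = 0, end = 4, ss = "N",
              residues = make_toy_chain("HHEE")$residues)
  expect_equal(geometry_feature(tie)[1:8], as.numeric(SS_ALPHABET == "H"))
  # mixed classes under an allegedly homogeneous fragment is an invariant breach
  mixed <- list(chain_id = "A", start = 0, end = 4, ss = "H",
                residues = make_toy_chain("HHEE")$residues)
  expect_error(geometry_feature(mixed), class = "scg_invariant_error")
})

test_that("the 74-d feature concatenates the three blocks", {
  ch <- random_chain(20)
  fr <- segment_by_ss(ch)
  pr <- uniform_profiles(20)
  frag <- fragment_at(fr, 1)
  x <- featurize(frag, pr)
  expect_length(x, 74L)
  expect_equal(x[1:20], unname(composition_feature(frag)))
  expect_equal(x[21:60], evolutionary_feature(frag, pr))
  expect_equal(x[61:74], geometry_feature(frag))
  expect_false(attr(x, "imputed_evolutionary"))

  x0 <- featurize(frag, NULL)
  expect_equal(x0[21:60], numeric(40))
  expect_true(attr(x0, "imputed_evolutionary"))
})

test_that("dimension law and composition simplex hold under fuzzing", {
  set.seed(33)
  for (rep in 1:25) {
    ch <- random_chain()
    fr <- segment_by_ss(ch)
    pr <- uniform_profiles(chain_length(ch))
    i <- sample(nrow(fr), 1)
    x <- featurize(fragment_at(fr, i), pr)
    expect_length(x, 74L)
    expect_true(all(is.finite(x)))
    expect_true(all(x[1:20] >= 0))
    expect_equal(sum(x[1:20]), 1, tolerance = 1e-9)
    expect_equal(sum(x[61:68]), 1)
  }
})

test_that("composition and averaging are invariant to residue order", {
  set.seed(34)
  ch <- random_chain(12)
  fr <- segment_uniform_random(ch, seed = 2)
  frag <- fragment_at(fr, 1)
  perm <- sample(nrow(frag$residues))
  shuffled <- frag
  shuffled$residues <- frag$residues[perm, ]
  expect_equal(composition_feature(shuffled), composition_feature(frag))
  expect_equal(geometry_feature(shuffled)[9:14], geometry_feature(frag)[9:14])
})

test_that("featurization is deterministic", {
  ch <- random_chain(15)
  pr <- uniform_profiles(15)
  fr <- segment_by_ss(ch)
  expect_identical(featurize_fragments(fr, pr), featurize_fragments(fr, pr))
})

test_that("standardization centers and scales and survives constant columns", {
  set.seed(35)
  X <- cbind(matrix(rnorm(50), 25), rep(2, 25))
  std <- fit_standardization(X)
  Xs <- apply_standardization(X, std)
  expect_equal(colMeans(Xs), numeric(3), tolerance = 1e-12)
  expect_equal(sd(Xs[, 1]), 1)
  expect_equal(Xs[, 3], numeric(25))     # constant column maps to zero
  expect_equal(apply_standardization(X[1, ], std), Xs[1, ])
})

test_that("feature matrices round-trip through TSV with sidecar", {
  ch <- random_chain(30)
  X <- featurize_fragments(segment_by_ss(ch), NULL)
  f <- tempfile(fileext = ".tsv")
  write_features(X, f)
  X2 <- read_features(f)
  expect_equal(unname(X2), unname(X), tolerance = 1e-12)
  expect_true(attr(X2, "imputed_evolutionary"))
  meta <- jsonlite::fromJSON(paste0(f, ".json"))
  expect_equal(meta$dim, 74L)
})
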