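# Synthetic fixture generator: toy chains with biophysically plausible
# secondary-structure runs and DSSP fields, matching on-disk DSSP/PSSM/HHM
# files in the exact dialects the readers expect, and cluster-structured
# fragment feature matrices for vocabulary-recovery tests.

#' Specification for the synthetic chain generator
#'
#' Chains are built as alternating secondary-structure runs: the first run
#' class is drawn from `class_weights`, each subsequent class from the
#' weights restricted to classes different from the previous one, and each
#' run length from a shifted geometric law with per-class mean
#' `run_mean` (support >= 1). Per-residue DSSP fields are drawn from
#' class-conditional Gaussians centred on textbook values (helix phi/psi
#' near -60/-45, strand near -120/135), clipped to legal ranges and rounded
#' to DSSP print precision.
#'
#' @param len_min,len_max Chain length range (residues); the target length
#'   is uniform on this range and the last run is truncated to fit.
#' @param class_weights Named numeric vector over the 8 SS classes.
#' @param run_mean Named numeric vector of mean run lengths per class.
#' @param break_prob Probability that a run boundary is also a chain break.
#' @return A list of class `scg_gen_spec`.
#' @export
chain_gen_spec <- function(len_min = 100L, len_max = 300L,
                           class_weights = c(H = 0.30, E = 0.20, C = 0.20,
                                             T = 0.12, S = 0.08, G = 0.06,
                                             B = 0.02, I = 0.02),
                           run_mean = c(H = 9, E = 5, G = 3, I = 4,
                                        T = 3, S = 2, B = 1, C = 4),
                           break_prob = 0) {
  stopifnot(setequal(names(class_weights), SS_ALPHABET),
            setequal(names(run_mean), SS_ALPHABET),
            len_min >= 2, len_max >= len_min)
  structure(list(len_min = as.integer(len_min), len_max = as.integer(len_max),
                 class_weights = class_weights / sum(class_weights),
                 run_mean = run_mean, break_prob = break_prob),
            class = "scg_gen_spec")
}

# class-conditional DSSP field laws: mean/sd per field
DSSP_FIELD_LAWS <- list(
  H = list(acc = c(40, 25), tco = c(0.9, 0.1), kappa = c(50, 10),
           alpha = c(50, 10), phi = c(-60, 10), psi = c(-45, 10)),
  E = list(acc = c(50, 30), tco = c(-0.9, 0.1), kappa = c(20, 10),
           alpha = c(170, 15), phi = c(-120, 20), psi = c(135, 20)),
  G = list(acc = c(50, 30), tco = c(0.7, 0.2), kappa = c(60, 15),
           alpha = c(60, 20), phi = c(-70, 15), psi = c(-20, 15)),
  I = list(acc = c(30, 20), tco = c(0.9, 0.1), kappa = c(50, 10),
           alpha = c(50, 15), phi = c(-57, 10), psi = c(-70, 10)),
  T = list(acc = c(80, 40), tco = c(0, 0.5), kappa = c(70, 30),
           alpha = c(50, 60), phi = c(-70, 40), psi = c(0, 60)),
  S = list(acc = c(90, 40), tco = c(0, 0.5), kappa = c(80, 30),
           alpha = c(0, 80), phi = c(-90, 50), psi = c(30, 80)),
  B = list(acc = c(60, 30), tco = c(-0.7, 0.2), kappa = c(40, 15),
           alpha = c(170, 15), phi = c(-110, 30), psi = c(140, 30)),
  C = list(acc = c(100, 50), tco = c(0, 0.6), kappa = c(80, 40),
           alpha = c(0, 90), phi = c(-90, 50), psi = c(60, 90)))

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

draw_field <- function(law, n) stats::rnorm(n, law[1], law[2])

# Draw one chain's SS runs + residues (rounded to DSSP print precision).
draw_chain <- function(spec, chain_id) {
  target <- sample(spec$len_min:spec$len_max, 1L)
  w <- spec$class_weights
  ss <- character(0); prev <- NULL
  while (length(ss) < target) {
    wc <- w
    if (!is.null(prev)) { wc[prev] <- 0; wc <- wc / sum(wc) }
    cl <- sample(SS_ALPHABET, 1L, prob = wc[SS_ALPHABET])
    len <- 1L + stats::rgeom(1L, prob = 1 / spec$run_mean[[cl]])
    ss <- c(ss, rep(cl, len)); prev <- cl
  }
  ss <- ss[seq_len(target)]
  n <- length(ss)
  aa <- sample(AA_ALPHABET, n, replace = TRUE)
  fld <- function(name, lo = -Inf, hi = Inf, digits = 1) {
    v <- vapply(ss, function(cl)
      draw_field(DSSP_FIELD_LAWS[[cl]][[name]], 1L), numeric(1))
    round(clip(v, lo, hi), digits)
  }
  # run boundaries eligible for chain breaks
  new_run <- c(FALSE, ss[-1] != ss[-n])
  brk <- new_run & stats::runif(n) < spec$break_prob
  scg_chain(chain_id = chain_id, aa = aa, ss = ss,
            acc = round(clip(fld("acc", 0, 999, 0), 0, 999)),
            tco = fld("tco", -1, 1, 3),
            kappa = fld("kappa", 0, 180, 1),
            alpha = fld("alpha", -180, 180, 1),
            phi = fld("phi", -180, 180, 1),
            psi = fld("psi", -180, 180, 1),
            break_before = brk, source = "synthetic")
}

# ---- writers for the on-disk dialects -------------------------------------

dssp_data_line <- function(lineno, resno, chain, aa, ss, acc, tco, kappa,
                           alpha, phi, psi) {
  paste0(sprintf("%5d%5d %s %s  %s", lineno, resno, chain, aa, ss),
         strrep(" ", 17),                       # structure detail + BP cols
         sprintf("%4d", as.integer(acc)),
         strrep(" ", 47),                       # hydrogen-bond columns
         sprintf("%6.3f%6.1f%6.1f%6.1f%6.1f", tco, kappa, alpha, phi, psi))
}

#' Write chains as a classic DSSP file
#'
#' Emits the fixed-width residue block (with preamble and the
#' "TOTAL NUMBER OF RESIDUES" header line) that [read_dssp()] parses.
#' Within-chain break flags become `!` rows; chain boundaries become `!*`
#' rows. Only the first character of each chain id fits the DSSP chain
#' column, so single-character ids round-trip exactly.
#'
#' @param chains List of [scg_chain()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dssp_file <- function(chains, path) {
  chains <- split_chains(chains)
  n_res <- sum(vapply(chains, chain_length, integer(1)))
  lines <- c(
    "==== Secondary Structure Definition by the program DSSP (synthetic fixture) ====",
    "REFERENCE  synthetic chain generator",
    sprintf("%5d%3d%3d%3d%3d TOTAL NUMBER OF RESIDUES, NUMBER OF CHAINS, NUMBER OF SS-BRIDGES(TOTAL,INTRACHAIN,INTERCHAIN)                .",
            n_res, length(chains), 0L, 0L, 0L),
    paste0("  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N",
           "    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI",
           "    X-CA   Y-CA   Z-CA"))
  lineno <- 0L
  for (ci in seq_along(chains)) {
    ch <- chains[[ci]]
    cid <- substr(ch$chain_id, 1, 1)
    res <- ch$residues
    if (ci > 1L) {
      lineno <- lineno + 1L
      lines <- c(lines, sprintf("%5d%5s   !*", lineno, ""))
    }
    for (i in seq_len(nrow(res))) {
      if (res$break_before[i]) {
        lineno <- lineno + 1L
        lines <- c(lines, sprintf("%5d%5s   !", lineno, ""))
      }
      lineno <- lineno + 1L
      lines <- c(lines, dssp_data_line(
        lineno, i, cid, res$aa[i], ifelse(res$ss[i] == "C", " ", res$ss[i]),
        res$acc[i], res$tco[i], res$kappa[i], res$alpha[i],
        res$phi[i], res$psi[i]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a raw PSSM matrix in PSI-BLAST ASCII dialect
#'
#' @param raw n x 20 integer matrix (PSI-BLAST column order).
#' @param aa One-letter sequence of length n.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm_file <- function(raw, aa, path) {
  header <- paste0("           ",
                   paste(sprintf("%3s", PSSM_AA_ORDER), collapse = ""),
                   "  ",
                   paste(sprintf("%3s", PSSM_AA_ORDER), collapse = ""))
  lines <- c("", "Last position-specific scoring matrix computed, weighted, and rounded",
             header)
  for (i in seq_len(nrow(raw))) {
    lines <- c(lines, paste0(
      sprintf("%5d %s ", i, aa[i]),
      paste(sprintf("%3d", raw[i, ]), collapse = ""),
      "  ",
      paste(sprintf("%4d", rep(0L, 20L)), collapse = ""),
      sprintf("  %5.2f %8.2f", 0, 0)))
  }
  writeLines(c(lines, ""), path)
  invisible(path)
}

#' Write HMM match-emission scores in HH-suite .hhm dialect
#'
#' @param scores n x 20 matrix of integer emission scores; `NA` entries are
#'   written as `*` (zero probability).
#' @param aa One-letter sequence of length n.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hhm_file <- function(scores, aa, path) {
  lines <- c("HHsearch 1.5", "NAME  synthetic", sprintf("LENG  %d", nrow(scores)),
             "#",
             paste0("NULL   ", paste(rep("3000", 20), collapse = "\t")),
             paste0("HMM    ", paste(HHM_AA_ORDER, collapse = "\t")),
             paste0("       ",
                    paste(c("M->M", "M->I", "M->D", "I->M", "I->I",
                            "D->M", "D->D", "Neff", "NeffI", "NeffD"),
                          collapse = "\t")),
             paste0("       0\t*\t*\t0\t*\t0\t*\t1000\t0\t0"))
  for (i in seq_len(nrow(scores))) {
    sc <- ifelse(is.na(scores[i, ]), "*", as.character(scores[i, ]))
    lines <- c(lines,
               paste0(aa[i], " ", i, "    ", paste(sc, collapse = "\t"),
                      "\t", i),
               paste0("       ",
                      paste(rep("0", 10), collapse = "\t")))
  }
  writeLines(c(lines, "//"), path)
  invisible(path)
}

# Draw integer profile scores tied to residue identity, then derive the
# in-memory profile pair from the quantized scores so files and memory
# agree exactly.
draw_profiles <- function(aa, noise_sd = 2) {
  n <- length(aa)
  raw <- matrix(as.integer(round(stats::rnorm(n * 20, -1, noise_sd))), n, 20L)
  own <- match(aa, PSSM_AA_ORDER)
  for (i in seq_len(n)) if (!is.na(own[i]))
    raw[i, own[i]] <- raw[i, own[i]] + 6L
  hmm_own <- match(aa, HHM_AA_ORDER)
  logits <- matrix(stats::rnorm(n * 20, 0, 1), n, 20L)
  for (i in seq_len(n)) if (!is.na(hmm_own[i]))
    logits[i, hmm_own[i]] <- logits[i, hmm_own[i]] + 4
  P <- softmax_rows(logits)
  hhm_scores <- matrix(as.integer(round(-1000 * log2(P))), n, 20L)
  hhm_scores[hhm_scores > 20000L] <- NA_integer_   # written as '*'
  list(pssm_raw = raw, hhm_scores = hhm_scores)
}

#' Generate one synthetic chain with matching DSSP/PSSM/HHM files
#'
#' Draws a chain from the generator spec and, when `dir` is given, writes
#' the three fixture files; the returned in-memory objects are derived from
#' the same quantized values the files carry, so re-reading the files
#' reproduces them exactly. Fully reproducible given the seed.
#'
#' @param spec A [chain_gen_spec()].
#' @param seed Integer seed.
#' @param chain_id Chain identifier (single character to round-trip through
#'   the DSSP chain column).
#' @param dir Output directory for fixture files, or `NULL` to skip
#'   writing.
#' @param uid Tag used for per-chain seed derivation (defaults to
#'   `chain_id`); give distinct uids to get independent chains with the
#'   same `chain_id`.
#' @return List with `chain` ([scg_chain()]), `profiles` (`scg_profiles`)
#'   and `files` (paths, or `NULL`).
#' @export
gen_chain <- function(spec, seed, chain_id = "A", dir = NULL,
                      uid = chain_id) {
  with_seed(derive_seed(seed, paste0("genchain:", uid)), {
    chain <- draw_chain(spec, chain_id)
    pr <- draw_profiles(chain$residues$aa)
    hmm <- ifelse(is.na(pr$hhm_scores), 0, 2^(-pr$hhm_scores / 1000))
    profiles <- make_profile_pair(normalize_pssm(pr$pssm_raw), hmm)
    files <- NULL
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      files <- list(dssp = file.path(dir, paste0(uid, ".dssp")),
                    pssm = file.path(dir, paste0(uid, ".pssm")),
                    hhm = file.path(dir, paste0(uid, ".hhm")))
      write_dssp_file(list(chain), files$dssp)
      write_pssm_file(pr$pssm_raw, chain$residues$aa, files$pssm)
      write_hhm_file(pr$hhm_scores, chain$residues$aa, files$hhm)
      chain$source <- files$dssp
    }
    list(chain = chain, profiles = profiles, files = files)
  })
}

#' Generate a corpus of synthetic chains
#'
#' @param spec A [chain_gen_spec()].
#' @param n_chains Number of chains.
#' @param seed Integer seed.
#' @param dir Optional output directory for per-chain fixture files.
#' @return List of [gen_chain()] results (chains carry uids `c0001`, ...).
#' @export
gen_corpus <- function(spec, n_chains, seed, dir = NULL) {
  lapply(seq_len(n_chains), function(i)
    gen_chain(spec, seed, chain_id = "A", dir = dir,
              uid = sprintf("c%04d", i)))
}

#' Generate a cluster-structured fragment feature fixture
#'
#' Gaussian mixture in 74 dimensions with `K_star` equally weighted
#' components whose centres are at least `separation` apart in Euclidean
#' distance. Rows are then made valid fragment features: the composition
#' block is projected onto the probability simplex and the one-hot
#' secondary-structure sub-block snapped to a valid one-hot.
#'
#' @param K_star Number of mixture components (>= 2).
#' @param m Number of samples.
#' @param separation Minimum pairwise centre distance.
#' @param within_sd Within-component standard deviation per dimension.
#' @param seed Integer seed.
#' @return List with `X` (m x 74), `labels` (1-based component ids) and
#'   `centers`.
#' @export
gen_fragment_mixture <- function(K_star, m, separation = 10, within_sd = 1,
                                 seed = 1L) {
  if (K_star < 2L) scg_error("K_star must be >= 2", "scg_config_error")
  p <- feature_dim()
  with_seed(derive_seed(seed, "mixture"), {
    centers <- matrix(stats::rnorm(K_star * p, sd = separation), K_star, p)
    dmin <- min(stats::dist(centers))
    if (dmin < separation) centers <- centers * (separation / dmin)
    labels <- sample.int(K_star, m, replace = TRUE)
    X <- centers[labels, , drop = FALSE] +
      matrix(stats::rnorm(m * p, sd = within_sd), m, p)
    # composition block onto the simplex
    comp <- pmax(X[, 1:20, drop = FALSE], 0)
    rs <- rowSums(comp)
    comp[rs == 0, ] <- 1 / 20
    rs[rs == 0] <- 1
    X[, 1:20] <- comp / rs
    # one-hot sub-block of the geometry block
    oh_cols <- 61:68
    amax <- max.col(X[, oh_cols, drop = FALSE], ties.method = "first")
    X[, oh_cols] <- 0
    X[cbind(seq_len(m), oh_cols[1] - 1L + amax)] <- 1
    list(X = X, labels = labels, centers = centers)
  })
}
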