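#' Extract one fragment with its residues
#'
#' @param fragments An `scg_fragments` data.frame from a segmenter.
#' @param i Fragment row index (1-based).
#' @return A list with `chain_id`, `start`, `end`, `ss` and `residues`
#'   (the covered rows of the chain's residue table).
#' @export
fragment_at <- function(fragments, i) {
  chain <- attr(fragments, "chain")
  row <- fragments[i, ]
  list(chain_id = row$chain_id, start = row$start, end = row$end,
       ss = row$ss,
       residues = chain$residues[(row$start + 1L):row$end, , drop = FALSE])
}

#' Amino-acid composition feature (20-d)
#'
#' Fraction of each standard amino acid among the fragment's standard
#' residues; `"X"` residues are excluded from both numerator and
#' denominator, and an all-`"X"` fragment yields the zero vector.
#'
#' @param fragment A fragment from [fragment_at()].
#' @return Named numeric vector of length 20 (order [AA_ALPHABET]).
#' @export
composition_feature <- function(fragment) {
  aa <- fragment$residues$aa
  if (length(aa) == 0L)
    scg_error("empty fragment", "scg_empty_input_error")
  aa <- aa[aa %in% AA_ALPHABET]
  v <- stats::setNames(numeric(20L), AA_ALPHABET)
  if (length(aa)) {
    tab <- table(factor(aa, levels = AA_ALPHABET))
    v[] <- as.numeric(tab) / length(aa)
  }
  v
}

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the first 20-column block (the per-position log-odds substitution
#' scores) of a `-out_ascii_pssm` file, one row per residue in sequence
#' order. Columns follow PSI-BLAST's A R N D C Q E G H I L K M F P S T W Y V
#' order.
#'
#' @param path Path to the `.pssm` file.
#' @param n_expected Optional declared sequence length; a mismatch with the
#'   parsed row count raises a format error.
#' @return Integer matrix of dimension n x 20.
#' @export
read_pssm <- function(path, n_expected = NULL) {
  lines <- readLines(path, warn = FALSE)
  data_rows <- grep("^\\s*[0-9]+\\s+[A-Za-z]\\s", lines)
  if (length(data_rows) == 0L)
    format_error(sprintf("no PSSM data rows found in %s", path))
  mat <- matrix(NA_integer_, length(data_rows), 20L)
  for (j in seq_along(data_rows)) {
    fields <- strsplit(trimws(lines[data_rows[j]]), "\\s+")[[1]]
    if (length(fields) < 22L)
      format_error(sprintf("line %d of %s: expected at least 20 score columns",
                           data_rows[j], path))
    sc <- suppressWarnings(as.integer(fields[3:22]))
    if (anyNA(sc))
      format_error(sprintf("line %d of %s: non-integer PSSM score",
                           data_rows[j], path))
    mat[j, ] <- sc
  }
  if (!is.null(n_expected) && nrow(mat) != n_expected)
    format_error(sprintf(
      "%s: %d PSSM rows but %d residues expected", path, nrow(mat), n_expected))
  colnames(mat) <- PSSM_AA_ORDER
  mat
}

#' Sigmoid-normalize raw PSSM scores
#'
#' Maps each log-odds score s to 1 / (1 + exp(-s)), bringing all entries
#' into (0, 1) for consistent scaling.
#'
#' @param raw Numeric matrix of raw PSSM scores.
#' @return Matrix of the same shape with entries in (0, 1).
#' @export
normalize_pssm <- function(raw) 1 / (1 + exp(-raw))

#' Read an HH-suite .hhm profile
#'
#' Extracts the 20 match-state emission scores per residue and converts
#' them to emission probabilities via 2^(-s/1000); the `*` marker (zero
#' probability) becomes 0. Columns follow the .hhm A C D E F G H I K L M N
#' P Q R S T V W Y order.
#'
#' @param path Path to the `.hhm` file.
#' @return Numeric matrix of dimension n x 20 with entries in [0, 1].
#' @export
read_hhm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hmm_start <- grep("^HMM\\s", lines)
  if (length(hmm_start) == 0L)
    format_error(sprintf("no 'HMM' header found in %s", path))
  block <- lines[seq(hmm_start[1] + 1L, length(lines))]
  emit_rows <- grep("^[A-Z]\\s+[0-9]+\\s", block)
  if (length(emit_rows) == 0L)
    format_error(sprintf("no match-emission rows found in %s", path))
  mat <- matrix(NA_real_, length(emit_rows), 20L)
  for (j in seq_along(emit_rows)) {
    fields <- strsplit(trimws(block[emit_rows[j]]), "\\s+")[[1]]
    if (length(fields) < 22L)
      format_error(sprintf(
        "truncated match-emission row %d in %s", emit_rows[j], path))
    sc <- fields[3:22]
    val <- ifelse(sc == "*", 0,
                  2^(-suppressWarnings(as.numeric(sc)) / 1000))
    if (anyNA(val))
      format_error(sprintf(
        "unparseable emission score in row %d of %s", emit_rows[j], path))
    mat[j, ] <- val
  }
  colnames(mat) <- HHM_AA_ORDER
  mat
}

#' Bundle per-chain evolutionary profiles
#'
#' @param pssm n x 20 sigmoid-normalized PSSM matrix (entries in (0, 1)).
#' @param hmm n x 20 HMM match-emission matrix (entries in [0, 1]).
#' @return A list of class `scg_profiles`.
#' @export
make_profile_pair <- function(pssm, hmm) {
  if (nrow(pssm) != nrow(hmm) || ncol(pssm) != 20L || ncol(hmm) != 20L)
    scg_error("pssm and hmm must both be n x 20 with matching n",
              "scg_shape_error")
  if (!all(is.finite(pssm)) || !all(is.finite(hmm)))
    scg_error("profile matrices must be finite", "scg_value_error")
  structure(list(pssm = pssm, hmm = hmm), class = "scg_profiles")
}

#' Load profiles from PSSM and HHM files
#'
#' @param pssm_path Path to a PSI-BLAST ASCII PSSM file.
#' @param hhm_path Path to an HH-suite .hhm file.
#' @return An `scg_profiles` pair with the PSSM sigmoid-normalized.
#' @export
load_profiles <- function(pssm_path, hhm_path) {
  make_profile_pair(normalize_pssm(read_pssm(pssm_path)), read_hhm(hhm_path))
}

#' Evolutionary conservation feature (40-d)
#'
#' Column means over the fragment's rows of the normalized PSSM (20 values)
#' followed by column means of the HMM emission matrix (20 values).
#'
#' @param fragment A fragment from [fragment_at()].
#' @param profiles An `scg_profiles` pair covering the fragment's chain.
#' @return Numeric vector of length 40, PSSM block first.
#' @export
evolutionary_feature <- function(fragment, profiles) {
  idx <- (fragment$start + 1L):fragment$end
  if (fragment$end > nrow(profiles$pssm))
    scg_error(sprintf(
      "fragment [%d,%d) outside profile range (n=%d)",
      fragment$start, fragment$end, nrow(profiles$pssm)), "scg_range_error")
  c(colMeans(profiles$pssm[idx, , drop = FALSE]),
    colMeans(profiles$hmm[idx, , drop = FALSE]))
}

# Mean of MAX_ASA, used when the residue identity ("X") has no tabulated
# maximum accessibility.
GENERIC_MAX_ASA <- mean(MAX_ASA)

# Normalize one angle column: the DSSP missing sentinel 360 maps to 0,
# everything else is divided by 180.
norm_angle <- function(x) ifelse(x == DSSP_MISSING_ANGLE, 0, x / 180)

#' Spatial geometry feature (14-d)
#'
#' Elements 1-8: one-hot encoding of the fragment's secondary-structure
#' class over the fixed H, B, E, G, I, T, S, C order (for non-homogeneous
#' ablation fragments, the majority class of the residues, ties broken by
#' alphabet order). Elements 9-14: fragment means of the normalized DSSP
#' fields ACC (relative accessibility, ACC divided by the residue's
#' theoretical maximum ASA and clipped to [0, 1]), TCO (as is), and
#' KAPPA/ALPHA/PHI/PSI divided by 180 with the 360 sentinel imputed to 0
#' before averaging.
#'
#' @param fragment A fragment from [fragment_at()].
#' @return Numeric vector of length 14.
#' @export
geometry_feature <- function(fragment) {
  res <- fragment$residues
  ss <- fragment$ss
  if (ss == "N") {
    tab <- table(factor(res$ss, levels = SS_ALPHABET))
    ss <- SS_ALPHABET[which.max(tab)]   # which.max: first (alphabet-order) tie-break
  } else {
    if (!all(res$ss == ss))
      scg_error("SS-segmented fragment contains mixed classes",
                "scg_invariant_error")
  }
  onehot <- as.numeric(SS_ALPHABET == ss)
  max_asa <- MAX_ASA[res$aa]
  max_asa[is.na(max_asa)] <- GENERIC_MAX_ASA
  rel_acc <- pmin(pmax(res$acc / max_asa, 0), 1)
  c(onehot,
    mean(rel_acc), mean(res$tco),
    mean(norm_angle(res$kappa)), mean(norm_angle(res$alpha)),
    mean(norm_angle(res$phi)), mean(norm_angle(res$psi)))
}

#' Full 74-dimensional fragment feature
#'
#' Concatenates the composition (20), evolutionary (40) and geometry (14)
#' blocks. With `profiles = NULL` the evolutionary block is imputed as
#' zeros and the attribute `imputed_evolutionary` records it, so a
#' vocabulary can be trained structure-only.
#'
#' @param fragment A fragment from [fragment_at()].
#' @param profiles An `scg_profiles` pair, or `NULL`.
#' @return Numeric vector of length 74 with attributes `layout` (block
#'   column ranges), `fragment_ref` and `imputed_evolutionary`.
#' @export
featurize <- function(fragment, profiles = NULL) {
  evo <- if (is.null(profiles)) numeric(40L)
         else evolutionary_feature(fragment, profiles)
  x <- c(composition_feature(fragment), evo, geometry_feature(fragment))
  names(x) <- NULL
  structure(x, layout = FEATURE_LAYOUT,
            fragment_ref = c(fragment$chain_id, fragment$start, fragment$end),
            imputed_evolutionary = is.null(profiles))
}

#' Featurize every fragment of a segmentation
#'
#' @param fragments An `scg_fragments` data.frame.
#' @param profiles An `scg_profiles` pair for the chain, or `NULL`.
#' @return Numeric matrix of dimension (n fragments) x 74.
#' @export
featurize_fragments <- function(fragments, profiles = NULL) {
  m <- nrow(fragments)
  X <- matrix(0, m, feature_dim())
  for (i in seq_len(m)) X[i, ] <- featurize(fragment_at(fragments, i), profiles)
  attr(X, "imputed_evolutionary") <- is.null(profiles)
  X
}

#' Fit per-dimension standardization parameters
#'
#' Column means and standard deviations of a fragment feature matrix;
#' constant columns get scale 1 so standardization never divides by zero.
#' The parameters are stored with a trained vocabulary and re-applied at
#' tokenization time.
#'
#' @param X Feature matrix (rows = fragments).
#' @return List with `center` and `scale` vectors.
#' @export
fit_standardization <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  list(center = center, scale = scale)
}

#' Apply standardization parameters
#'
#' @param X Feature matrix or single 74-vector.
#' @param std Parameters from [fit_standardization()].
#' @return Standardized matrix/vector of the same shape.
#' @export
apply_standardization <- function(X, std) {
  if (is.null(dim(X))) return((X - std$center) / std$scale)
  sweep(sweep(X, 2, std$center, "-"), 2, std$scale, "/")
}

#' Write/read a fragment feature matrix with a JSON sidecar
#'
#' The matrix is stored as TSV; the sidecar records the block layout,
#' imputation flag and optional standardization parameters.
#'
#' @param X Feature matrix.
#' @param path Output TSV path; the sidecar is written to `<path>.json`.
#' @param std Optional standardization parameters to record.
#' @return `path`, invisibly.
#' @export
write_features <- function(X, path, std = NULL) {
  utils::write.table(X, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  meta <- list(n = nrow(X), dim = ncol(X), layout = FEATURE_LAYOUT,
               imputed_evolutionary = isTRUE(attr(X, "imputed_evolutionary")),
               standardization = std)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  X <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(X) <- NULL
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  attr(X, "imputed_evolutionary") <- isTRUE(meta$imputed_evolutionary)
  X
}
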