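#' Construct a protein chain record
#'
#' A chain is the unit every downstream stage (segmentation, featurization,
#' tokenization) operates on: an ordered table of residues, each carrying a
#' one-letter amino-acid code, an 8-state secondary-structure class and the
#' six numeric per-residue DSSP fields (ACC, TCO, KAPPA, ALPHA, PHI, PSI).
#'
#' @param chain_id Chain identifier (single string).
#' @param aa Character vector of one-letter amino-acid codes ("X" for
#'   nonstandard residues).
#' @param ss Character vector of secondary-structure classes, each one of
#'   H, B, E, G, I, T, S, C.
#' @param acc,tco,kappa,alpha,phi,psi Numeric vectors of the DSSP fields
#'   (ACC in squared angstroms, angles in degrees with 360 as the missing
#'   sentinel, TCO dimensionless). Default 0.
#' @param break_before Logical vector; `TRUE` marks a residue preceded by a
#'   chain break, so no fragment may span the boundary.
#' @param source Provenance string (file path or "synthetic").
#'
#' @return An object of class `scg_chain`: a list with `chain_id`, `source`
#'   and `residues` (a data.frame with one row per residue and a 0-based
#'   `seq_index` column).
#' @export
scg_chain <- function(chain_id, aa, ss,
                      acc = 0, tco = 0, kappa = 0, alpha = 0,
                      phi = 0, psi = 0,
                      break_before = FALSE, source = "synthetic") {
  n <- length(aa)
  if (n == 0L) scg_error("chain must contain at least one residue",
                         "scg_empty_input_error")
  if (length(ss) != n)
    scg_error("aa and ss must have equal length", "scg_shape_error")
  bad <- setdiff(unique(ss), SS_ALPHABET)
  if (length(bad))
    scg_error(sprintf("invalid secondary-structure class: %s",
                      paste(bad, collapse = ", ")), "scg_value_error")
  rec <- function(x) rep_len(x, n)
  residues <- data.frame(
    seq_index = seq_len(n) - 1L,
    aa = aa, ss = ss,
    acc = rec(acc), tco = rec(tco), kappa = rec(kappa),
    alpha = rec(alpha), phi = rec(phi), psi = rec(psi),
    break_before = rec(break_before),
    stringsAsFactors = FALSE)
  structure(list(chain_id = chain_id, residues = residues, source = source),
            class = "scg_chain")
}

#' @export
print.scg_chain <- function(x, ...) {
  cat(sprintf("<scg_chain %s: %d residues, source=%s>\n",
              x$chain_id, nrow(x$residues), x$source))
  invisible(x)
}

#' Number of residues in a chain
#' @param chain An `scg_chain`.
#' @return Integer residue count.
#' @export
chain_length <- function(chain) nrow(chain$residues)

# Map a DSSP AA-column letter to the internal one-letter code: lower-case
# letters are DSSP's SS-bonded cysteine labels (a-z -> C); anything outside
# the 20 standard residues becomes "X".
map_dssp_aa <- function(aa) {
  out <- ifelse(aa %in% letters, "C", aa)
  ifelse(out %in% AA_ALPHABET, out, "X")
}

# Map the DSSP structure summary letter to the 8-class alphabet: a blank is
# coil ("C"); any letter outside the alphabet also falls back to coil.
map_dssp_ss <- function(ss) {
  out <- ifelse(ss == " " | ss == "", "C", ss)
  ifelse(out %in% SS_ALPHABET, out, "C")
}

#' Read a classic DSSP output file
#'
#' Parses the fixed-width residue block of classic (non-mmCIF) DSSP output:
#' everything after the `"  #  RESIDUE AA STRUCTURE ..."` header line. The
#' structure summary letter is mapped onto the 8-class alphabet with blank
#' mapped to coil `"C"`; chain-break rows (amino acid `"!"`) emit no residue
#' but mark the following residue so segmentation never bridges the break.
#' The six numeric fields ACC, TCO, KAPPA, ALPHA, PHI and PSI are captured
#' per residue; the 360 missing-angle sentinel is retained as parsed.
#'
#' @param path Path to a `.dssp` file.
#' @return A list of [scg_chain()] objects, one per chain identifier, in
#'   order of first appearance. The attribute `header_total_residues` holds
#'   the residue count printed in the "TOTAL NUMBER OF RESIDUES" header
#'   line when present, else `NA`.
#' @export
read_dssp <- function(path) {
  if (!file.exists(path))
    format_error(sprintf("DSSP file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) format_error(sprintf("empty DSSP file: %s", path))
  hdr <- grep("^\\s*#\\s+RESIDUE\\s+AA\\s+STRUCTURE", lines)
  if (length(hdr) == 0L)
    format_error(sprintf(
      "no '#  RESIDUE AA STRUCTURE' header found in %s: not classic DSSP output",
      path))
  hdr <- hdr[1]

  total <- NA_integer_
  tot_line <- grep("TOTAL NUMBER OF RESIDUES", lines[seq_len(hdr)], value = TRUE)
  if (length(tot_line)) {
    m <- regmatches(tot_line[1], regexpr("[0-9]+", tot_line[1]))
    if (length(m)) total <- as.integer(m)
  }

  chains <- list()          # chain_id -> list of row lists
  breaks <- list()          # chain_id -> pending-break flag
  pending_break <- FALSE
  for (i in seq(hdr + 1L, length.out = max(0L, length(lines) - hdr))) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    aa_raw <- substr(ln, 14, 14)
    if (aa_raw == "!") { pending_break <- TRUE; next }   # break rows can be short
    if (nchar(ln) < 17L)
      format_error(sprintf("line %d of %s: truncated DSSP data row", i, path))
    cid <- substr(ln, 12, 12)
    if (cid == " ") cid <- "_"
    num <- function(a, b, name) {
      v <- suppressWarnings(as.numeric(substr(ln, a, b)))
      if (is.na(v))
        format_error(sprintf("line %d of %s: unparseable %s field", i, path, name))
      v
    }
    row <- list(
      aa = map_dssp_aa(aa_raw),
      ss = map_dssp_ss(substr(ln, 17, 17)),
      acc = num(35, 38, "ACC"), tco = num(86, 91, "TCO"),
      kappa = num(92, 97, "KAPPA"), alpha = num(98, 103, "ALPHA"),
      phi = num(104, 109, "PHI"), psi = num(110, 115, "PSI"),
      break_before = pending_break && length(chains[[cid]]) > 0L)
    pending_break <- FALSE
    chains[[cid]] <- c(chains[[cid]], list(row))
  }
  if (length(chains) == 0L)
    format_error(sprintf("no residue rows found in %s", path))

  out <- lapply(names(chains), function(cid) {
    rows <- chains[[cid]]
    g <- function(f) unlist(lapply(rows, `[[`, f), use.names = FALSE)
    scg_chain(chain_id = cid, aa = g("aa"), ss = g("ss"),
              acc = g("acc"), tco = g("tco"), kappa = g("kappa"),
              alpha = g("alpha"), phi = g("phi"), psi = g("psi"),
              break_before = g("break_before"), source = path)
  })
  attr(out, "header_total_residues") <- total
  out
}

# 3-letter -> 1-letter residue codes for the 20 standard amino acids.
AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V")

#' Extract a chain's one-letter sequence from a PDB file
#'
#' Reads the CA-bearing residues of one chain from a PDB file and returns
#' their one-letter sequence. Nonstandard residues (e.g. MSE) become `"X"`.
#' Used only to cross-check DSSP/sequence agreement; when the two disagree
#' the DSSP record is authoritative (see [validate_chain_sequence()]).
#'
#' @param path Path to a PDB file.
#' @param chain_id Chain identifier to extract.
#' @return One-letter sequence string.
#' @export
read_pdb_chain <- function(path, chain_id) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  atoms <- pdb$atom
  sel <- atoms$chain == chain_id & atoms$elety == "CA" &
    atoms$type %in% c("ATOM", "HETATM")
  if (!chain_id %in% atoms$chain)
    scg_error(sprintf("chain '%s' not present in %s", chain_id, path),
              "scg_lookup_error")
  if (!any(sel))
    scg_error(sprintf("chain '%s' in %s has no CA atoms", chain_id, path),
              "scg_empty_input_error")
  res3 <- atoms$resid[sel]
  one <- unname(AA_THREE_TO_ONE[res3])
  one[is.na(one)] <- "X"
  paste(one, collapse = "")
}

#' Cross-check a DSSP chain against a PDB-derived sequence
#'
#' Emits a warning if the DSSP amino-acid column disagrees with the PDB
#' sequence; the DSSP record is taken as authoritative either way.
#'
#' @param chain An [scg_chain()].
#' @param pdb_sequence One-letter sequence string from [read_pdb_chain()].
#' @return The chain, invisibly.
#' @export
validate_chain_sequence <- function(chain, pdb_sequence) {
  dssp_seq <- paste(chain$residues$aa, collapse = "")
  if (!identical(dssp_seq, pdb_sequence))
    warning(sprintf(
      "chain %s: DSSP sequence differs from PDB sequence (DSSP kept as authoritative)",
      chain$chain_id), call. = FALSE)
  invisible(chain)
}

#' Split structures into single-chain units
#'
#' Accepts a single chain or a (possibly nested) list of chains and returns
#' a flat list of single-chain units in input order; already-split input
#' passes through unchanged.
#'
#' @param chains An `scg_chain` or list of them.
#' @return Flat list of `scg_chain` objects.
#' @export
split_chains <- function(chains) {
  if (inherits(chains, "scg_chain")) return(list(chains))
  out <- list()
  for (el in chains) out <- c(out, split_chains(el))
  out
}

#' Dump chains as a residue-level TSV table
#'
#' @param chains List of [scg_chain()] objects.
#' @param path Output file; when `NULL` the data.frame is returned instead.
#' @return The residue table (invisibly when written to file).
#' @export
chains_to_tsv <- function(chains, path = NULL) {
  chains <- split_chains(chains)
  tab <- do.call(rbind, lapply(chains, function(ch)
    cbind(chain_id = ch$chain_id,
          ch$residues[c("seq_index", "aa", "ss", "acc", "tco",
                        "kappa", "alpha", "phi", "psi")])))
  if (is.null(path)) return(tab)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
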