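# Fixtures are built in code: toy chains with chosen SS strings, raw DSSP
# text lines, tiny PDB files, and uniform profile pairs.

make_toy_chain <- function(ss_string, aa = NULL, chain_id = "A", ...) {
  ss <- strsplit(ss_string, "")[[1]]
  if (is.null(aa)) aa <- rep("A", length(ss))
  scg_chain(chain_id = chain_id, aa = aa, ss = ss, ...)
}

# raw classic-DSSP text from per-residue fields (blank ss letters allowed)
dssp_text <- function(aa, ss_letters, chain = "A", acc = 0, tco = 0,
                      kappa = 0, alpha = 0, phi = 0, psi = 0,
                      break_after = integer(0), total_override = NULL) {
  n <- length(aa)
  rec <- function(x) rep_len(x, n)
  acc <- rec(acc); tco <- rec(tco); kappa <- rec(kappa)
  alpha <- rec(alpha); phi <- rec(phi); psi <- rec(psi)
  lines <- c(
    "==== Secondary Structure Definition by the program DSSP ====",
    sprintf("%5d%3d%3d%3d%3d TOTAL NUMBER OF RESIDUES, NUMBER OF CHAINS, NUMBER OF SS-BRIDGES(TOTAL,INTRACHAIN,INTERCHAIN) .",
            if (is.null(total_override)) n else total_override, 1L, 0L, 0L, 0L),
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI    X-CA   Y-CA   Z-CA")
  k <- 0L
  for (i in seq_len(n)) {
    k <- k + 1L
    lines <- c(lines, scglang:::dssp_data_line(
      k, i, chain, aa[i], ss_letters[i], acc[i], tco[i], kappa[i],
      alpha[i], phi[i], psi[i]))
    if (i %in% break_after) {
      k <- k + 1L
      lines <- c(lines, sprintf("%5d%5s   !", k, ""))
    }
  }
  lines
}

write_dssp_text <- function(...) {
  f <- tempfile(fileext = ".dssp")
  writeLines(dssp_text(...), f)
  f
}

pdb_atom_line <- function(serial, resn, chain, resno, rec = "ATOM") {
  sprintf("%-6s%5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          rec, serial, resn, chain, resno, resno * 3.8, 0, 0)
}

write_toy_pdb <- function(resn, chain = "A", rec = "ATOM") {
  f <- tempfile(fileext = ".pdb")
  lines <- vapply(seq_along(resn), function(i)
    pdb_atom_line(i, resn[i], chain, i,
                  rec = if (length(rec) > 1) rec[i] else rec), character(1))
  writeLines(c(lines, "END"), f)
  f
}

# constant-valued profile pair for a chain of length n
uniform_profiles <- function(n, pssm_val = 0.5, hmm_val = 0.25) {
  make_profile_pair(matrix(pssm_val, n, 20), matrix(hmm_val, n, 20))
}

# random chain with legal random SS classes and DSSP fields
random_chain <- function(n = NULL, chain_id = "A") {
  if (is.null(n)) n <- sample(5:80, 1)
  scg_chain(chain_id = chain_id,
            aa = sample(AA_ALPHABET, n, replace = TRUE),
            ss = sample(SS_ALPHABET, n, replace = TRUE,
                        prob = c(6, 1, 4, 1, 1, 2, 1, 5)),
            acc = round(runif(n, 0, 200)),
            tco = round(runif(n, -1, 1), 3),
            kappa = round(runif(n, 0, 180), 1),
            alpha = round(runif(n, -180, 180), 1),
            phi = round(runif(n, -180, 180), 1),
            psi = round(runif(n, -180, 180), 1))
}
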