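#' Alphabets and normalization constants
#'
#' Fixed alphabets used throughout the package: the 8-state secondary
#' structure alphabet (DSSP classes, with coil stored as the letter "C"),
#' the 20 standard amino acids in alphabetical one-letter order, and the
#' per-residue theoretical maximum accessible surface areas used to turn
#' DSSP ACC values into relative accessibilities.
#'
#' @name alphabets
NULL

#' @rdname alphabets
#' @format `SS_ALPHABET` is a character vector of the 8 secondary-structure
#'   classes in the fixed order H, B, E, G, I, T, S, C.
#' @export
SS_ALPHABET <- c("H", "B", "E", "G", "I", "T", "S", "C")

#' @rdname alphabets
#' @format `AA_ALPHABET` is a character vector of the 20 standard one-letter
#'   amino-acid codes in alphabetical order.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# PSI-BLAST ASCII PSSM column order (header row of -out_ascii_pssm).
PSSM_AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# HH-suite .hhm match-emission column order.
HHM_AA_ORDER <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Theoretical maximum ASA per residue (Tien et al. 2013), in squared
# angstroms; used to clip DSSP ACC into relative accessibility [0, 1].
MAX_ASA <- c(A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225,
             E = 223, G = 104, H = 224, I = 197, L = 201, K = 236,
             M = 224, F = 240, P = 159, S = 155, T = 172, W = 285,
             Y = 263, V = 174)

# DSSP sentinel for an undefined angle.
DSSP_MISSING_ANGLE <- 360.0

# Feature block layout of the 74-dimensional fragment vector.
FEATURE_LAYOUT <- list(
  composition  = c(1L, 20L),   # 1-based inclusive column ranges
  evolutionary = c(21L, 60L),
  geometry     = c(61L, 74L)
)

#' Dimension of the fragment feature vector
#'
#' @return Integer, 74: 20 composition + 40 evolutionary + 14 geometry.
#' @export
feature_dim <- function() {
  sum(vapply(FEATURE_LAYOUT, function(r) r[2] - r[1] + 1L, integer(1)))
}
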