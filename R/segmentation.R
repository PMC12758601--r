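#' Segment a chain into secondary-structure fragments
#'
#' The core segmentation of the coarse-grained language: consecutive
#' residues sharing the same secondary-structure class are grouped into one
#' fragment, so each fragment is a maximal same-SS run. A chain break always
#' starts a new fragment, even when the SS class matches across it, because
#' fragments must be spatially contiguous.
#'
#' @param chain An [scg_chain()].
#' @return A data.frame of class `scg_fragments` with columns `chain_id`,
#'   `start` (0-based inclusive), `end` (exclusive), `ss`, `length`;
#'   fragments are ordered and tile `[0, chain length)` exactly. The source
#'   chain is attached as attribute `chain`.
#' @export
segment_by_ss <- function(chain) {
  res <- chain$residues
  n <- nrow(res)
  if (n == 0L) scg_error("cannot segment an empty chain", "scg_empty_input_error")
  new_run <- c(TRUE, res$ss[-1] != res$ss[-n] | res$break_before[-1])
  starts <- which(new_run)
  ends <- c(starts[-1], n + 1L) - 1L           # inclusive, 1-based
  make_fragments(chain, starts - 1L, ends, res$ss[starts])
}

make_fragments <- function(chain, start0, end0, ss) {
  out <- data.frame(chain_id = chain$chain_id, start = as.integer(start0),
                    end = as.integer(end0), ss = ss,
                    length = as.integer(end0 - start0),
                    stringsAsFactors = FALSE)
  attr(out, "chain") <- chain
  class(out) <- c("scg_fragments", "data.frame")
  out
}

# Break-delimited blocks of a chain as (start, end) half-open 0-based pairs.
chain_blocks <- function(chain) {
  res <- chain$residues
  n <- nrow(res)
  bstart <- c(0L, which(res$break_before) - 1L)
  bend <- c(which(res$break_before) - 1L, n)
  Map(c, bstart, bend)
}

# Tile the half-open interval [a, b) with consecutive lengths `lens`
# (recycled/truncated as needed); trailing remainder becomes its own
# fragment. Returns 0-based (start, end) rows.
tile_lengths <- function(a, b, lens) {
  starts <- integer(0); ends <- integer(0)
  pos <- a; i <- 1L
  while (pos < b) {
    L <- if (i <= length(lens)) lens[i] else b - pos
    e <- min(pos + L, b)
    starts <- c(starts, pos); ends <- c(ends, e)
    pos <- e; i <- i + 1L
  }
  cbind(starts, ends)
}

#' Uniform random fragment segmentation (ablation)
#'
#' One fragment length is drawn uniformly from the integers 3..60 per chain
#' and the chain is divided evenly into fragments of that length; only the
#' final fragment of each break-delimited block may be shorter. Fragments
#' are not SS-homogeneous, so their class is recorded as `"N"`.
#'
#' @param chain An [scg_chain()].
#' @param seed Integer seed; the draw is made from an independent stream
#'   derived from `(seed, chain_id)` so corpus results are order-independent.
#' @return An `scg_fragments` data.frame (see [segment_by_ss()]).
#' @export
segment_uniform_random <- function(chain, seed) {
  if (chain_length(chain) == 0L)
    scg_error("cannot segment an empty chain", "scg_empty_input_error")
  L <- with_seed(derive_seed(seed, paste0("uniform:", chain$chain_id)),
                 sample(3:60, 1L))
  rows <- do.call(rbind, lapply(chain_blocks(chain), function(b)
    tile_lengths(b[1], b[2], rep(L, ceiling((b[2] - b[1]) / L)))))
  make_fragments(chain, rows[, 1], rows[, 2], "N")
}

#' Dynamic random fragment segmentation (ablation)
#'
#' Fragment lengths are drawn i.i.d. uniformly from 3..60, one per
#' segmentation step, until the chain is exhausted; the final fragment of a
#' block may be shorter than 3. Deterministic given the seed.
#'
#' @inheritParams segment_uniform_random
#' @return An `scg_fragments` data.frame.
#' @export
segment_dynamic_random <- function(chain, seed) {
  n <- chain_length(chain)
  if (n == 0L) scg_error("cannot segment an empty chain", "scg_empty_input_error")
  rows <- with_seed(derive_seed(seed, paste0("dynamic:", chain$chain_id)), {
    do.call(rbind, lapply(chain_blocks(chain), function(b) {
      starts <- integer(0); ends <- integer(0); pos <- b[1]
      while (pos < b[2]) {
        L <- sample(3:60, 1L)
        e <- min(pos + L, b[2])
        starts <- c(starts, pos); ends <- c(ends, e); pos <- e
      }
      cbind(starts, ends)
    }))
  })
  make_fragments(chain, rows[, 1], rows[, 2], "N")
}

#' Secondary-structure length-shuffling segmentation (ablation)
#'
#' Collects the fragment lengths produced by [segment_by_ss()], permutes
#' them uniformly at random (within each break-delimited block), and tiles
#' the chain with the shuffled lengths. The multiset of fragment lengths is
#' identical to SS-based segmentation; only their order changes.
#'
#' @inheritParams segment_uniform_random
#' @return An `scg_fragments` data.frame.
#' @export
segment_length_shuffle <- function(chain, seed) {
  fr <- segment_by_ss(chain)
  rows <- with_seed(derive_seed(seed, paste0("shuffle:", chain$chain_id)), {
    do.call(rbind, lapply(chain_blocks(chain), function(b) {
      lens <- fr$length[fr$start >= b[1] & fr$end <= b[2]]
      lens <- if (length(lens) > 1L) sample(lens) else lens
      tile_lengths(b[1], b[2], lens)
    }))
  })
  make_fragments(chain, rows[, 1], rows[, 2], "N")
}

#' Resolve a segmenter by name
#'
#' @param name One of `"ss"`, `"uniform"`, `"dynamic"`, `"shuffle"`.
#' @param seed Integer seed used by the random segmenters (ignored by
#'   `"ss"`).
#' @return A function mapping a chain to its fragments.
#' @export
get_segmenter <- function(name, seed = 1L) {
  switch(name,
    ss      = function(chain) segment_by_ss(chain),
    uniform = function(chain) segment_uniform_random(chain, seed),
    dynamic = function(chain) segment_dynamic_random(chain, seed),
    shuffle = function(chain) segment_length_shuffle(chain, seed),
    scg_error(sprintf("unknown segmenter '%s'", name), "scg_value_error"))
}

#' Corpus compression statistics
#'
#' Summarizes how much shorter fragment sentences are than the underlying
#' residue sequences: per-chain residue and fragment counts, the
#' corpus-level mean length ratio (total residues / total fragments), and
#' the number of sentences exceeding a truncation length.
#'
#' @param chains List of [scg_chain()] objects.
#' @param segmenter Segmenter name (see [get_segmenter()]).
#' @param seed Seed forwarded to random segmenters.
#' @param truncation Sentence length above which a sentence counts as
#'   truncated (default 512).
#' @return A list with `per_chain` (data.frame: chain_id, n_residues,
#'   n_fragments), `mean_length_ratio`, and `n_truncated`.
#' @export
compression_stats <- function(chains, segmenter = "ss", seed = 1L,
                              truncation = 512L) {
  chains <- split_chains(chains)
  if (length(chains) == 0L)
    scg_error("empty corpus", "scg_empty_input_error")
  seg <- get_segmenter(segmenter, seed)
  per <- do.call(rbind, lapply(chains, function(ch) {
    fr <- seg(ch)
    data.frame(chain_id = ch$chain_id, n_residues = chain_length(ch),
               n_fragments = nrow(fr), stringsAsFactors = FALSE)
  }))
  list(per_chain = per,
       mean_length_ratio = sum(per$n_residues) / sum(per$n_fragments),
       n_truncated = sum(per$n_fragments > truncation))
}

#' Write fragments as a BED-like TSV
#'
#' @param fragments An `scg_fragments` data.frame (or rbind of several).
#' @param path Output path.
#' @return The written data.frame, invisibly.
#' @export
fragments_to_tsv <- function(fragments, path) {
  tab <- as.data.frame(fragments)[c("chain_id", "start", "end", "ss", "length")]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
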