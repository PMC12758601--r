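#' Serialize a chain into a coarse-grained token sentence
#'
#' Runs the full per-chain pipeline: segment, featurize each fragment,
#' standardize with the vocabulary's stored parameters, encode, and
#' quantize. Tokens follow fragment order along the sequence, one token per
#' fragment, so a sentence is never longer than the chain.
#'
#' @param chain An [scg_chain()].
#' @param vocab An `scg_vocab` (see [train_vqvae()], [train_kmeans_vocab()]).
#' @param profiles An `scg_profiles` pair for the chain, or `NULL` to impute
#'   the evolutionary block as zeros.
#' @param segmenter Segmenter name (see [get_segmenter()]).
#' @param seed Seed forwarded to random segmenters.
#' @return A list of class `scg_sentence`: `chain_id`, `tokens` (0-based
#'   integer vector), `fragments` (data.frame start/end/ss) and `vocab_id`
#'   (the vocabulary manifest hash).
#' @export
tokenize_chain <- function(chain, vocab, profiles = NULL, segmenter = "ss",
                           seed = 1L) {
  fr <- get_segmenter(segmenter, seed)(chain)
  X <- featurize_fragments(fr, profiles)
  if (ncol(X) != length(vocab$standardization$center))
    scg_error("feature layout does not match the vocabulary manifest",
              "scg_version_error")
  tokens <- tokenize_features(vocab, X)
  structure(list(chain_id = chain$chain_id, tokens = tokens,
                 fragments = as.data.frame(fr)[c("start", "end", "ss")],
                 vocab_id = vocab$hash),
            class = "scg_sentence")
}

#' @export
print.scg_sentence <- function(x, ...) {
  cat(sprintf("<scg_sentence %s: %d tokens>\n %s\n", x$chain_id,
              length(x$tokens), paste(x$tokens, collapse = " ")))
  invisible(x)
}

#' Write / read a token corpus
#'
#' Plain-text corpus, one protein per line: `chain_id<TAB>t1 t2 ... tn`
#' with space-separated integer tokens, after a single `#` header line.
#' Sentences longer than `truncation` tokens are cut at write time and the
#' truncation is counted; reading is lossless for untruncated sentences.
#'
#' @param sentences List of `scg_sentence` objects.
#' @param path Corpus file path.
#' @param truncation Maximum sentence length kept at write time
#'   (default 512).
#' @return `write_corpus()` invisibly returns a list with `n_sentences` and
#'   `n_truncated`; `read_corpus()` returns a list of `scg_sentence`
#'   objects (without fragment provenance).
#' @export
write_corpus <- function(sentences, path, truncation = 512L) {
  n_trunc <- 0L
  lines <- c("# chain_id\ttokens")
  for (s in sentences) {
    tok <- s$tokens
    if (length(tok) > truncation) {
      tok <- tok[seq_len(truncation)]
      n_trunc <- n_trunc + 1L
    }
    lines <- c(lines, paste0(s$chain_id, "\t", paste(tok, collapse = " ")))
  }
  writeLines(lines, path)
  invisible(list(n_sentences = length(sentences), n_truncated = n_trunc))
}

#' @rdname write_corpus
#' @param vocab Optional `scg_vocab`; when given, any token at or above its
#'   K raises a corpus/vocabulary mismatch error.
#' @export
read_corpus <- function(path, vocab = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  K <- if (is.null(vocab)) NULL else nrow(vocab$codebook)
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    tokens <- if (length(parts) < 2L || !nzchar(trimws(parts[2]))) integer(0)
              else as.integer(strsplit(trimws(parts[2]), " ")[[1]])
    if (!is.null(K) && length(tokens) && max(tokens) >= K)
      scg_error(sprintf(
        "corpus token %d out of range for vocabulary of size %d",
        max(tokens), K), "scg_version_error")
    structure(list(chain_id = parts[1], tokens = tokens, fragments = NULL,
                   vocab_id = if (is.null(vocab)) NA_character_ else vocab$hash),
              class = "scg_sentence")
  })
}
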