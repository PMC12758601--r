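# Internal helpers: error constructors and seed derivation.

scg_error <- function(msg, class) {
  stop(structure(class = c(class, "scg_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

format_error <- function(msg) scg_error(msg, "scg_format_error")

# Deterministic 31-bit hash of a string (polynomial rolling hash); used to
# derive independent per-chain seeds so corpus-level results do not depend
# on chain order.
string_hash31 <- function(s) {
  codes <- utf8ToInt(s)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

# Derive a child seed from a global seed and a string tag, staying below
# 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 7919 + string_hash31(tag)) %% 2147483647)
}

# Evaluate expr with a local RNG state seeded from `seed`, restoring the
# caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# md5 of a JSON-serializable object, via a temporary file (tools::md5sum is
# file-based); used for vocabulary manifest hashes.
object_md5 <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}
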