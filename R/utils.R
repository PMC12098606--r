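#' @keywords internal
"_PACKAGE"

# Canonical form for class labels: lower-case, trimmed, edge punctuation
# stripped, internal whitespace / hyphens / slashes collapsed to "_".
normalize_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", x)
  x <- gsub("[[:space:]/-]+", "_", x)
  x
}

# Normalisation applied to span text before embedding: lower-case, collapse
# whitespace, strip leading/trailing punctuation (but keep internal "+", "/").
normalize_span_text <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[[:space:]]+", " ", x)
  trimws(gsub("^[[:punct:][:space:]]+|[[:punct:][:space:]]+$", "", x))
}

# Deterministic sub-seed derivation so one run seed can fan out to
# independent components without correlated streams. Kept below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset) * 16807) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ctx <- function(msg, ..., call. = FALSE) stop(sprintf(msg, ...), call. = call.)
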