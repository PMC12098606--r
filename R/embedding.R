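#' Deterministic character n-gram hashing embedder
#'
#' Embeds short texts as L2-normalised bags of hashed character n-grams
#' (default range 3-5, dimension 1024). The embedder is deterministic and
#' dependency-free, so the full pipeline is bit-reproducible; it satisfies
#' the embedding-backend contract required by the classifiers: `embed(texts)`
#' returns one unit-norm row per non-empty text.
#'
#' Texts are normalised (lower-case, collapsed whitespace, edge punctuation
#' stripped) and padded with one space on each side so that strings shorter
#' than the minimum n-gram length, e.g. single-digit classes, still produce
#' at least one n-gram.
#'
#' @param dim Number of hashing buckets (embedding dimension).
#' @param ngram Integer `c(min, max)` character n-gram range.
#' @return An object of class `embedding_backend` with fields `embed`
#'   (function: character vector -> matrix), `dim`, and `identity` (a string
#'   identifying the embedder for model serialisation).
#' @export
hashing_embedder <- function(dim = 1024L, ngram = c(3L, 5L)) {
  dim <- as.integer(dim)
  stopifnot(dim >= 2L, length(ngram) == 2L, ngram[1] >= 1L, ngram[2] >= ngram[1])
  backend <- list(
    embed = function(texts) hash_embed(texts, dim, ngram),
    dim = dim,
    identity = sprintf("hashing_ngram/v1 dim=%d ngram=%d-%d", dim, ngram[1], ngram[2])
  )
  structure(backend, class = "embedding_backend")
}

#' @export
print.embedding_backend <- function(x, ...) {
  cat("<embedding_backend>", x$identity, "\n")
  invisible(x)
}

# Polynomial rolling hash of a character n-gram (integer code points),
# multiplier 31, reduced mod 2^31-1 each step so doubles stay exact.
hash_ngram_codes <- function(codes, dim) {
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% 2147483647
  as.integer(h %% dim) + 1L
}

hash_embed <- function(texts, dim, ngram) {
  texts <- as.character(texts)
  out <- matrix(0, nrow = length(texts), ncol = dim)
  for (i in seq_along(texts)) {
    t0 <- normalize_span_text(texts[i])
    if (!nzchar(t0)) next
    padded <- paste0(" ", t0, " ")
    codes <- utf8ToInt(padded)
    nc <- length(codes)
    counts <- numeric(dim)
    for (n in seq(ngram[1], ngram[2])) {
      if (nc < n) next
      for (s in seq_len(nc - n + 1L)) {
        b <- hash_ngram_codes(codes[s:(s + n - 1L)], dim)
        counts[b] <- counts[b] + 1
      }
    }
    nrm <- sqrt(sum(counts^2))
    if (nrm > 0) out[i, ] <- counts / nrm
  }
  out
}

# Internal helper used by tests: an embedder that looks texts up in a fixed
# table of hand-built vectors (rows are L2-normalised on the way in).
lookup_embedder <- function(table) {
  mat <- do.call(rbind, table)
  mat <- mat / sqrt(rowSums(mat^2))
  structure(list(
    embed = function(texts) {
      idx <- match(normalize_span_text(texts), normalize_span_text(names(table)))
      if (anyNA(idx)) stop_ctx("lookup_embedder: unknown text")
      mat[idx, , drop = FALSE]
    },
    dim = ncol(mat),
    identity = "lookup/v1"
  ), class = "embedding_backend")
}
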