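#' Interchange formats
#'
#' JSONL (one JSON object per line) is the canonical interchange: report
#' batches are `{"report_id": ..., "text": ...}`, classifier example sets
#' are `{"text": ..., "label": ...}`, and pipeline outputs are
#' `{"report_id","feature_id","predicted_class","qa_confidence",
#' "classifier_confidence"}`. CSV with the same columns is accepted for
#' report input. Fitted classifier models serialise to a versioned JSON
#' format that records the embedder identity.
#'
#' @name io
NULL

read_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) as.data.frame(jsonlite::fromJSON(l),
                                                  stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

write_jsonl <- function(df, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  for (i in seq_len(nrow(df))) {
    writeLines(jsonlite::toJSON(as.list(df[i, , drop = FALSE]),
                                auto_unbox = TRUE, digits = NA, na = "null"),
               con)
  }
  invisible(path)
}

#' Read a report batch (JSONL or CSV)
#'
#' @param path File with `report_id` and `text` fields; the format is
#'   chosen by extension (`.csv` vs anything else = JSONL).
#' @return Data frame with `report_id`, `text`.
#' @export
read_reports <- function(path) {
  df <- if (grepl("\\.csv$", path, ignore.case = TRUE))
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  else read_jsonl(path)
  if (!all(c("report_id", "text") %in% names(df)))
    stop_ctx("report file '%s' must have report_id and text fields", path)
  if (anyDuplicated(df$report_id))
    stop_ctx("duplicate report_id '%s' in batch", df$report_id[duplicated(df$report_id)][1])
  df[c("report_id", "text")]
}

#' Read a labelled example set (JSONL with text and label fields)
#'
#' @param path JSONL file.
#' @return Data frame with `text`, `label`.
#' @export
read_examples <- function(path) {
  df <- read_jsonl(path)
  if (!all(c("text", "label") %in% names(df)))
    stop_ctx("example file '%s' must have text and label fields", path)
  df[c("text", "label")]
}

#' Write pipeline output records as JSONL
#'
#' @param records Output-record data frame from [run_batch()].
#' @param path Destination file.
#' @export
write_records <- function(records, path) write_jsonl(records, path)

#' @rdname write_records
#' @export
read_records <- function(path) read_jsonl(path)

embedder_from_identity <- function(identity) {
  m <- regmatches(identity,
                  regexec("^hashing_ngram/v1 dim=([0-9]+) ngram=([0-9]+)-([0-9]+)$",
                          identity))[[1]]
  if (length(m) != 4)
    stop_ctx("cannot reconstruct embedder '%s'; only the hashing embedder serialises",
             identity)
  hashing_embedder(dim = as.integer(m[2]),
                   ngram = c(as.integer(m[3]), as.integer(m[4])))
}

#' Serialise / restore a fitted classifier model
#'
#' Models are written as versioned JSON including the embedder identity, so
#' a restored model reproduces the original predictions exactly.
#'
#' @param model A [fit_prototype()] or [fit_contrastive()] model backed by
#'   the hashing embedder.
#' @param path Destination / source file.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "prototype_model")) {
    obj <- list(format = "clinenrich_model/1", type = "prototype",
                embedder = model$embedder$identity, classes = model$classes,
                labels = model$labels, mode = model$mode,
                feature_id = model$feature_id,
                embeddings = model$embeddings)
  } else if (inherits(model, "contrastive_model")) {
    obj <- list(format = "clinenrich_model/1", type = "contrastive",
                embedder = model$embedder$identity, classes = model$classes,
                feature_id = model$feature_id, config = model$config,
                W = model$W, head_weights = model$head$weights,
                head_bias = model$head$bias, loss_history = model$loss_history)
  } else stop_ctx("unsupported model class '%s'", class(model)[1])
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "clinenrich_model/1"))
    stop_ctx("'%s' is not a clinenrich model file", path)
  embedder <- embedder_from_identity(obj$embedder)
  if (obj$type == "prototype") {
    structure(list(embeddings = as.matrix(obj$embeddings), labels = obj$labels,
                   classes = obj$classes, mode = obj$mode,
                   feature_id = obj$feature_id, embedder = embedder),
              class = "prototype_model")
  } else if (obj$type == "contrastive") {
    structure(list(W = as.matrix(obj$W),
                   head = list(weights = as.matrix(obj$head_weights),
                               bias = obj$head_bias),
                   classes = obj$classes, config = obj$config,
                   loss_history = obj$loss_history,
                   feature_id = obj$feature_id, embedder = embedder),
              class = "contrastive_model")
  } else stop_ctx("unknown model type '%s'", obj$type)
}
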