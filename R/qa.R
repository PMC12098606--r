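#' Extractive question answering over a report
#'
#' Stage 1 of the pipeline locates the answer to a feature's clinical
#' question inside a free-text report and returns it as a *span*: a
#' substring with 0-based half-open character offsets and a confidence in
#' \[0,1\]. Extraction is strictly extractive — a backend may only return
#' text that is verbatim present in the report, which is what rules out
#' hallucinated values. Unanswerable reports yield the empty span.
#'
#' @name qa-stage
NULL

#' Construct an answer span
#'
#' @param text Extracted substring ("" for the empty span).
#' @param start,end 0-based half-open character offsets (-1/-1 for the
#'   empty span).
#' @param confidence Real in \[0,1\].
#' @return An object of class `answer_span`.
#' @export
answer_span <- function(text, start, end, confidence) {
  stopifnot(confidence >= 0, confidence <= 1)
  structure(list(text = text, start = as.integer(start), end = as.integer(end),
                 confidence = confidence), class = "answer_span")
}

#' @rdname answer_span
#' @export
empty_span <- function(confidence = 0) answer_span("", -1L, -1L, confidence)

#' @rdname answer_span
#' @export
is_empty_span <- function(span) !nzchar(span$text)

#' @export
print.answer_span <- function(x, ...) {
  if (is_empty_span(x)) cat(sprintf("<answer_span> (empty), confidence %.3f\n", x$confidence))
  else cat(sprintf("<answer_span> \"%s\" [%d,%d), confidence %.3f\n",
                   x$text, x$start, x$end, x$confidence))
  invisible(x)
}

span_is_substring <- function(span, context) {
  if (is_empty_span(span)) return(span$start == -1L && span$end == -1L)
  span$start >= 0 && span$end <= nchar(context) &&
    identical(substr(context, span$start + 1L, span$end), span$text)
}

#' Wrap an answer function as a verified extractive backend
#'
#' The wrapper enforces the no-hallucination guarantee: every span the
#' backend returns must be a verbatim substring of the context at the
#' reported offsets (or the empty span). A violating backend raises an
#' error instead of leaking generated text.
#'
#' @param answer_fn `function(context, question, feature)` returning an
#'   [answer_span()], optionally with an attribute `candidates` holding a
#'   list of further candidate spans (multi-mention reports).
#' @param name Backend name used in error messages.
#' @return An object of class `extractive_backend`.
#' @export
extractive_backend <- function(answer_fn, name = "custom") {
  stopifnot(is.function(answer_fn))
  structure(list(
    answer = function(context, question, feature) {
      span <- answer_fn(context, question, feature)
      cands <- attr(span, "candidates") %||% list(span)
      for (s in cands) {
        if (!inherits(s, "answer_span") || !span_is_substring(s, context))
          stop_ctx("backend '%s' violated the substring invariant", name)
      }
      span
    },
    name = name
  ), class = "extractive_backend")
}

# Regex occurrences of a literal form with non-alphanumeric boundaries
# (handles "3" in "3+" but not "3" in "30"). Returns start positions (1-based)
# and lengths.
find_form <- function(text, form) {
  pat <- paste0("(?<![[:alnum:]])", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", form),
                "(?![[:alnum:]])")
  m <- gregexpr(pat, text, perl = TRUE, ignore.case = TRUE)[[1]]
  if (m[1] == -1) return(NULL)
  data.frame(start = as.integer(m), len = attr(m, "match.length"))
}

# Earliest match among a set of forms; among equal starts the longest wins.
earliest_match <- function(text, forms, classes = NULL) {
  best <- NULL
  for (i in seq_along(forms)) {
    hits <- find_form(text, forms[i])
    if (is.null(hits)) next
    h <- hits[1, ]
    if (is.null(best) || h$start < best$start ||
        (h$start == best$start && h$len > best$len)) {
      best <- list(start = h$start, len = h$len,
                   class = if (!is.null(classes)) classes[i] else NA_character_)
    }
  }
  best
}

#' Rule-based extractive backend
#'
#' A deterministic reference backend: it finds each occurrence of one of the
#' feature's aliases, scans a bounded window after the alias for a value
#' drawn from the feature's class surface forms (confidence 0.95) or, for
#' bounded numeric features, a bare in-range integer (confidence 0.5), and
#' returns the matched value span. Reports mentioning the feature several
#' times yield one candidate span per mention; downstream severity
#' resolution picks the winner. No value in the window yields the empty span.
#'
#' @param context Report text.
#' @param feature A [feature_schema()].
#' @param window Characters scanned after each alias occurrence.
#' @return An [answer_span()]; the attribute `candidates` holds all candidate
#'   spans in order of occurrence.
#' @export
rule_based_extract <- function(context, feature, window = 60L) {
  if (!nzchar(context)) return(empty_span())
  aliases <- feature$aliases[order(-nchar(feature$aliases))]
  occ <- NULL
  for (a in aliases) {
    hits <- find_form(context, a)
    if (!is.null(hits)) occ <- rbind(occ, hits)
  }
  if (is.null(occ)) return(empty_span())
  occ <- occ[order(occ$start, -occ$len), , drop = FALSE]
  # drop alias hits nested in a longer alias hit at the same place ("figo"
  # inside "figo stage")
  keep <- rep(TRUE, nrow(occ))
  last_end <- 0L
  for (i in seq_len(nrow(occ))) {
    if (occ$start[i] <= last_end) keep[i] <- FALSE
    else last_end <- occ$start[i] + occ$len[i] - 1L
  }
  occ <- occ[keep, , drop = FALSE]

  vt <- value_pattern_table(feature)
  spans <- list()
  for (i in seq_len(nrow(occ))) {
    wstart <- occ$start[i] + occ$len[i]
    wtext <- substr(context, wstart, min(nchar(context), wstart + window - 1L))
    wtext <- sub("[.!?\n].*$", "", wtext)   # never scan past the sentence end
    hit <- earliest_match(wtext, vt$form, vt$class)
    conf <- 0.95
    if (is.null(hit) && feature$value_kind == "bounded_numeric") {
      m <- regexpr("(?<![[:alnum:]])[0-9]+(?![[:alnum:]])", wtext, perl = TRUE)
      if (m[1] != -1) {
        val <- as.integer(substr(wtext, m, m + attr(m, "match.length") - 1L))
        if (!is.na(val) && val >= feature$numeric_range[1] &&
            val <= feature$numeric_range[2]) {
          hit <- list(start = as.integer(m), len = attr(m, "match.length"))
          conf <- 0.5
        }
      }
    }
    if (is.null(hit)) next
    s1 <- wstart + hit$start - 1L            # 1-based start in context
    span <- answer_span(substr(context, s1, s1 + hit$len - 1L),
                        s1 - 1L, s1 - 1L + hit$len, conf)
    spans[[length(spans) + 1L]] <- span
  }
  if (!length(spans)) return(empty_span())
  primary <- spans[[1L]]
  attr(primary, "candidates") <- spans
  primary
}

#' The rule-based backend as an `extractive_backend`
#'
#' @param window Scan window passed to [rule_based_extract()].
#' @return An `extractive_backend`.
#' @export
rule_based_backend <- function(window = 60L) {
  extractive_backend(function(context, question, feature)
    rule_based_extract(context, feature, window = window),
    name = "rule_based")
}

#' Ask a feature's question of a report
#'
#' @param backend An [extractive_backend()].
#' @param report A list with `report_id` and `text`.
#' @param feature A [feature_schema()].
#' @return The verified [answer_span()].
#' @export
ask <- function(backend, report, feature) {
  stopifnot(inherits(backend, "extractive_backend"))
  tryCatch(
    backend$answer(report$text, feature$question, feature),
    error = function(e) stop_ctx("QA failed for report '%s', feature '%s': %s",
                                 report$report_id %||% "?", feature$feature_id,
                                 conditionMessage(e))
  )
}

#' Adapt a local span-prediction model as an extractive backend
#'
#' Wraps a locally available question-answering span predictor. The model is
#' supplied as a callable `function(context, question)` returning a list with
#' `start`, `end` (0-based half-open character offsets; -1/-1 when
#' unanswerable), `start_prob`, `end_prob`, and `no_answer_prob`. The span
#' confidence is defined as the product of the start- and end-token
#' probabilities renormalised against the no-answer score:
#' `p = sp*ep / (sp*ep + no_answer_prob)`, which is monotone in the model's
#' certainty. Offsets are verified against the context like any backend.
#'
#' @param model_ref The callable described above. Passing a file path raises
#'   an error explaining that the model artifact must be installed locally
#'   and wrapped as a callable; no model is downloaded.
#' @return An `extractive_backend`.
#' @export
transformer_adapter <- function(model_ref) {
  if (!is.function(model_ref))
    stop_ctx(paste0(
      "transformer_adapter: no local model callable supplied. Install the QA ",
      "model artifact offline and wrap it as function(context, question) ",
      "returning start/end offsets with start_prob, end_prob, no_answer_prob."))
  extractive_backend(function(context, question, feature) {
    out <- model_ref(context, question)
    if (is.null(out) || (out$start %||% -1L) < 0)
      return(empty_span(confidence = 0))
    sp <- out$start_prob %||% 1
    ep <- out$end_prob %||% 1
    na <- out$no_answer_prob %||% 0
    conf <- if (sp * ep + na > 0) sp * ep / (sp * ep + na) else 0
    answer_span(substr(context, out$start + 1L, out$end), out$start, out$end,
                min(1, max(0, conf)))
  }, name = "transformer_adapter")
}
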