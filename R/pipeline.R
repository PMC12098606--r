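#' Pipeline configuration
#'
#' @param qa_confidence_threshold Spans whose extraction confidence is below
#'   this value (default 0.10) are routed straight to `"not_present"`, as are
#'   blank spans.
#' @param classifier_kind `"prototype"` or `"contrastive"`; recorded for
#'   provenance (the model passed to [run_pipeline()] decides).
#' @param softmax_temperature Temperature of the prototype confidence.
#' @param seed Run seed; all component randomness is derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(qa_confidence_threshold = 0.10,
                            classifier_kind = c("prototype", "contrastive"),
                            softmax_temperature = 1, seed = 1L) {
  stopifnot(qa_confidence_threshold >= 0, qa_confidence_threshold <= 1,
            softmax_temperature > 0)
  list(qa_confidence_threshold = qa_confidence_threshold,
       classifier_kind = match.arg(classifier_kind),
       softmax_temperature = softmax_temperature,
       seed = as.integer(seed))
}

#' Route a span: abstain or pass to the classifier
#'
#' Blank spans and spans whose QA confidence is below the threshold are
#' automatically assigned the `"not_present"` class; everything else passes
#' to the classifier unchanged.
#'
#' @param span An [answer_span()].
#' @param config A [pipeline_config()].
#' @return `list(decision = "not_present")` or
#'   `list(decision = "pass", span = span)`.
#' @export
route <- function(span, config = pipeline_config()) {
  if (is_empty_span(span) || span$confidence < config$qa_confidence_threshold)
    list(decision = NOT_PRESENT)
  else list(decision = "pass", span = span)
}

#' Run the two-stage pipeline on one report and feature
#'
#' Extracts candidate spans with the backend, routes blank/low-confidence
#' candidates to `"not_present"`, classifies the surviving span texts into
#' the feature's closed vocabulary, and — when a report mentions the feature
#' several times — resolves the classified candidates to the most clinically
#' severe class. The emitted record contains only the predicted class and
#' the two confidences, never any report text.
#'
#' @param report List with `report_id` and `text`.
#' @param feature A [feature_schema()].
#' @param backend An [extractive_backend()].
#' @param classifier_model A fitted [fit_prototype()] or [fit_contrastive()]
#'   model (may be `NULL`, in which case every non-routed span is still
#'   impossible to classify and the record falls back to `"not_present"`).
#' @param config A [pipeline_config()].
#' @return A one-row data frame: `report_id`, `feature_id`,
#'   `predicted_class`, `qa_confidence`, `classifier_confidence`
#'   (1.0 when routing decided).
#' @export
run_pipeline <- function(report, feature, backend, classifier_model,
                         config = pipeline_config()) {
  span <- ask(backend, report, feature)
  cands <- attr(span, "candidates") %||% list(span)
  surviving <- Filter(function(s) identical(route(s, config)$decision, "pass"), cands)

  record <- function(label, qa_conf, cls_conf) {
    data.frame(report_id = report$report_id %||% NA_character_,
               feature_id = feature$feature_id,
               predicted_class = label,
               qa_confidence = qa_conf,
               classifier_confidence = cls_conf,
               stringsAsFactors = FALSE)
  }
  if (!length(surviving) || is.null(classifier_model))
    return(record(NOT_PRESENT, if (length(cands)) max(vapply(cands, `[[`, 0, "confidence")) else 0, 1.0))

  preds <- lapply(surviving, function(s)
    classify_span(classifier_model, s$text,
                  temperature = config$softmax_temperature))
  labels <- vapply(preds, `[[`, "", "label")
  win_label <- resolve_most_severe(feature, labels)
  i <- which(labels == win_label)[1]
  record(win_label, surviving[[i]]$confidence, preds[[i]]$confidence)
}

#' Run the pipeline over a batch of reports
#'
#' @param reports Data frame with `report_id`, `text`, or a list of report
#'   lists.
#' @param feature A [feature_schema()].
#' @inheritParams run_pipeline
#' @return A data frame of output records, one row per report.
#' @export
run_batch <- function(reports, feature, backend, classifier_model,
                      config = pipeline_config()) {
  if (is.data.frame(reports))
    reports <- lapply(seq_len(nrow(reports)), function(i)
      list(report_id = reports$report_id[i], text = reports$text[i]))
  out <- lapply(reports, run_pipeline, feature = feature, backend = backend,
                classifier_model = classifier_model, config = config)
  do.call(rbind, out)
}
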