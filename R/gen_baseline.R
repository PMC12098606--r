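#' Generative-model baseline plumbing
#'
#' The generative comparison arm replaces the extractive QA stage with a
#' prompted text-generating model: a role-based prompt pair (system prompt +
#' instruction prompt with the question, the report as context, and the
#' biomarker name filled in) is sent to a generative backend, and the
#' generated text is post-parsed with a deterministic rule — the text
#' following the first occurrence of a biomarker alias, up to the end of the
#' sentence or line. Generated output equal to the sentinel `"NaN"`, or
#' containing no biomarker alias, is treated as unanswerable and routed to
#' `"not_present"`. Parsed candidates are classified with the prototype
#' cosine classifier. The language model itself is an external plug-in; a
#' deterministic mock backend is included so the loop is testable offline.
#'
#' @name gen-baseline
NULL

default_system_template <- paste(
  "You are a clinical information extraction assistant.",
  "Answer only from the report text. Reply in the form {biomarker}: <answer>.",
  "If the report does not state the {biomarker} result, reply NaN.")

default_instruction_template <- paste(
  "Question: {question}", "Report: {context}",
  "State the {biomarker} result exactly as written in the report,",
  "or NaN if it cannot be answered.")

fill_placeholders <- function(template, values) {
  for (key in names(values))
    template <- gsub(paste0("{", key, "}"), values[[key]], template, fixed = TRUE)
  left <- regmatches(template, regexpr("\\{[a-z_]+\\}", template))
  if (length(left))
    stop_ctx("prompt template has unresolved placeholder %s", left[1])
  template
}

#' Build the prompt pair for a feature and report
#'
#' @param feature A [feature_schema()].
#' @param context Report text (may be empty).
#' @param system_template,instruction_template Template strings with
#'   `{question}`, `{context}`, `{biomarker}` placeholders; the packaged
#'   defaults follow the role-based system/instruction structure.
#' @return List with `system_prompt`, `instruction_prompt`.
#' @export
build_prompt <- function(feature, context,
                         system_template = default_system_template,
                         instruction_template = default_instruction_template) {
  values <- list(question = feature$question, context = context,
                 biomarker = feature$display_name)
  if (!grepl("{context}", instruction_template, fixed = TRUE))
    stop_ctx("instruction template lacks the {context} placeholder")
  list(system_prompt = fill_placeholders(system_template, values),
       instruction_prompt = fill_placeholders(instruction_template, values))
}

#' Parse generated text into a candidate value or unanswerable
#'
#' Applies the packaged extraction rule to untrusted generated output: the
#' text following the first biomarker-alias occurrence, up to the end of the
#' sentence or line, with leading separator punctuation stripped. The
#' sentinel `"NaN"`, empty output, or output containing no alias is
#' unanswerable. Never raises.
#'
#' @param output Generated text (any string).
#' @param feature A [feature_schema()].
#' @return List with `answerable` (logical) and `candidate` (string or `NA`).
#' @export
parse_generation <- function(output, feature) {
  if (is.null(output) || !length(output) || is.na(output[1]))
    return(list(answerable = FALSE, candidate = NA_character_))
  output <- as.character(output)[1]
  if (!nzchar(trimws(output)) || identical(trimws(output), "NaN"))
    return(list(answerable = FALSE, candidate = NA_character_))
  aliases <- unique(c(feature$aliases, tolower(feature$display_name)))
  aliases <- aliases[order(-nchar(aliases))]
  for (a in aliases) {
    hit <- find_form(output, a)
    if (is.null(hit)) next
    after <- substr(output, hit$start[1] + hit$len[1], nchar(output))
    after <- sub("[.!?\n].*$", "", after)          # up to sentence/line end
    after <- sub("^[[:space:]:=-]+", "", after)    # strip separator
    after <- trimws(after)
    if (!nzchar(after) || identical(after, "NaN"))
      return(list(answerable = FALSE, candidate = NA_character_))
    return(list(answerable = TRUE, candidate = after))
  }
  list(answerable = FALSE, candidate = NA_character_)
}

#' Deterministic mock generative backend
#'
#' Echoes `"<biomarker>: <value>"` where the value is looked up in a fixed
#' table keyed by report text, or produced by running the rule-based
#' extractor on the context embedded in the instruction prompt. Used to
#' exercise the generative loop end to end without any model weights.
#'
#' @param registry A `schema_registry` used to recover the feature from the
#'   prompt's biomarker field.
#' @return A function `generate(prompt_pair, feature, context)` returning a
#'   string (the `generative_backend` contract: outputs are untrusted).
#' @export
mock_generative_backend <- function(registry) {
  function(prompt_pair, feature, context) {
    span <- rule_based_extract(context, feature)
    if (is_empty_span(span)) "NaN"
    else sprintf("%s: %s.", feature$display_name, span$text)
  }
}

#' Run the generative baseline on one report and feature
#'
#' Prompt assembly, generation through the supplied backend hook, regex
#' post-parsing, and prototype classification of the parsed candidate.
#'
#' @inheritParams run_pipeline
#' @param generate Backend hook `function(prompt_pair, feature, context)`.
#' @param prototype_model A [fit_prototype()] model for the feature.
#' @return A one-row output-record data frame (as [run_pipeline()]).
#' @export
run_generative <- function(report, feature, generate, prototype_model,
                           config = pipeline_config()) {
  prompts <- build_prompt(feature, report$text)
  out <- generate(prompts, feature, report$text)
  parsed <- parse_generation(out, feature)
  rec <- function(label, conf) {
    data.frame(report_id = report$report_id %||% NA_character_,
               feature_id = feature$feature_id, predicted_class = label,
               qa_confidence = NA_real_, classifier_confidence = conf,
               stringsAsFactors = FALSE)
  }
  if (!parsed$answerable || is.null(prototype_model))
    return(rec(NOT_PRESENT, 1.0))
  pred <- classify_prototype(prototype_model, parsed$candidate,
                             temperature = config$softmax_temperature)
  rec(pred$label, pred$confidence)
}
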