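#' Feature schemas and the schema registry
#'
#' A *feature schema* describes one clinical feature (biomarker, stage, or
#' measurement): the natural-language question used to query a report, the
#' surface forms (aliases) that locate mentions of the feature, the closed
#' class vocabulary the pipeline is allowed to emit, and a total severity
#' order over the classes used to resolve conflicting mentions. A *registry*
#' is a validated collection of feature schemas keyed by `feature_id`.
#'
#' Every vocabulary contains the reserved class `"not_present"`, which is the
#' least severe class by contract: it encodes reports where the feature is
#' absent or not positively identifiable, and it can never win a severity
#' resolution against a substantive class.
#'
#' @name feature-schema
NULL

NOT_PRESENT <- "not_present"

#' Construct a single feature schema
#'
#' @param feature_id Identifier, unique within a registry.
#' @param question Natural-language question, e.g. "What is the p53 status?".
#' @param classes Character vector of class labels (canonicalised to
#'   lower-case). `"not_present"` is injected if missing.
#' @param aliases Surface forms used to locate mentions in free text.
#' @param severity Classes ordered least to most severe, excluding
#'   `"not_present"`. Defaults to the order of `classes`. The token
#'   `"@numeric"` expands to the ascending numeric family of a
#'   `bounded_numeric` feature.
#' @param display_name Human-readable name.
#' @param value_kind One of `"categorical"`, `"ordinal"`, `"bounded_numeric"`.
#' @param numeric_range Integer `c(lo, hi)` for `bounded_numeric` features;
#'   the integers in the range are appended to the vocabulary as classes.
#' @return An object of class `feature_schema`.
#' @export
feature_schema <- function(feature_id, question, classes, aliases,
                           severity = NULL, display_name = feature_id,
                           value_kind = c("categorical", "ordinal", "bounded_numeric"),
                           numeric_range = NULL) {
  value_kind <- match.arg(value_kind)
  feature_id <- normalize_label(feature_id)
  if (!nzchar(feature_id)) stop_ctx("feature_id must be non-empty")
  if (!length(aliases)) stop_ctx("feature '%s': aliases must be non-empty", feature_id)

  classes <- normalize_label(classes)
  if (anyDuplicated(classes))
    stop_ctx("feature '%s': duplicate class label '%s'",
             feature_id, classes[duplicated(classes)][1])
  numeric_classes <- character(0)
  if (value_kind == "bounded_numeric") {
    if (is.null(numeric_range) || length(numeric_range) != 2)
      stop_ctx("feature '%s': bounded_numeric requires numeric_range = c(lo, hi)", feature_id)
    numeric_classes <- as.character(seq(numeric_range[1], numeric_range[2]))
  }
  classes <- c(setdiff(classes, NOT_PRESENT), numeric_classes)
  if (anyDuplicated(classes))
    stop_ctx("feature '%s': duplicate class label '%s'",
             feature_id, classes[duplicated(classes)][1])
  if (!all(nzchar(classes)))
    stop_ctx("feature '%s': empty class label after normalisation", feature_id)

  if (is.null(severity)) {
    severity <- classes
  } else {
    severity <- normalize_label(severity)
    at <- which(severity == "numeric")  # "@numeric" normalises to "numeric"
    if (length(at) == 1L)
      severity <- append(severity[-at], numeric_classes, after = at - 1L)
    if (!setequal(severity, classes) || length(severity) != length(classes))
      stop_ctx("feature '%s': severity order is not a permutation of its classes",
               feature_id)
  }

  structure(list(
    feature_id = feature_id,
    display_name = display_name,
    question = question,
    aliases = tolower(as.character(aliases)),
    value_kind = value_kind,
    numeric_range = numeric_range,
    classes = c(NOT_PRESENT, classes),
    severity = severity  # excludes not_present, which is minimal by contract
  ), class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cat(sprintf("<feature_schema> %s (%s)\n", x$feature_id, x$value_kind))
  cat("  question:", x$question, "\n")
  cat("  classes: ", paste(utils::head(x$classes, 12), collapse = ", "),
      if (length(x$classes) > 12) sprintf(", ... (%d total)", length(x$classes)) else "",
      "\n", sep = "")
  invisible(x)
}

#' Load a schema registry from a configuration document
#'
#' Reads a YAML document (or an already-parsed list with the same structure)
#' describing one feature per entry and returns a validated registry.
#'
#' @param config Path to a YAML file, or a list with a `features` element.
#' @return A `schema_registry`: a named list of [feature_schema()] objects.
#' @export
load_registry <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_ctx("registry config must be a file path or a list")
  entries <- config$features %||% list()
  feats <- lapply(entries, function(e) {
    feature_schema(
      feature_id = e$feature_id %||% stop_ctx("registry entry without feature_id"),
      question = e$question %||% stop_ctx("feature '%s': missing question", e$feature_id),
      classes = unlist(e$classes) %||% stop_ctx("feature '%s': missing classes", e$feature_id),
      aliases = unlist(e$aliases),
      severity = if (!is.null(e$severity)) unlist(e$severity),
      display_name = e$display_name %||% e$feature_id,
      value_kind = e$value_kind %||% "categorical",
      numeric_range = if (!is.null(e$numeric_range)) unlist(e$numeric_range)
    )
  })
  ids <- vapply(feats, `[[`, "", "feature_id")
  if (anyDuplicated(ids))
    stop_ctx("duplicate feature_id '%s' in registry", ids[duplicated(ids)][1])
  names(feats) <- ids
  structure(feats, class = "schema_registry")
}

#' The packaged default registry
#'
#' Returns the registry of 23 clinical features shipped with the package:
#' 18 endometrial/breast/staging features (FIGO stage, grade, p53, MMR and
#' the four MMR proteins, myometrial and lymphovascular invasion, HER2, ER,
#' PR, TNM T/N/M and edition, blast cell percentage) plus 5 lung features
#' (ALK, CgA, EGFR, synaptophysin, TTF1). Bounded numeric features (blast
#' cell percentage 0-100, ER/PR 0-8) expose one class per integer alongside
#' their categorical classes.
#'
#' @return A `schema_registry`.
#' @export
default_registry <- function() {
  path <- system.file("extdata", "default_registry.yaml", package = "clinenrich")
  if (!nzchar(path)) stop_ctx("packaged registry not found; is clinenrich installed?")
  load_registry(path)
}

#' @export
print.schema_registry <- function(x, ...) {
  cat(sprintf("<schema_registry> %d features: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

get_feature <- function(registry, feature_id) {
  feature_id <- normalize_label(feature_id)
  f <- registry[[feature_id]]
  if (is.null(f)) stop_ctx("unknown feature '%s'", feature_id)
  f
}

#' Resolve multiple mentions to the most clinically severe class
#'
#' When a report mentions a feature several times (for instance quoting an
#' earlier report and amending it), the most clinically severe class is
#' retained. `"not_present"` never wins over a substantive class.
#'
#' @param feature A [feature_schema()].
#' @param labels Non-empty character vector of class labels from the
#'   feature's vocabulary.
#' @return The maximal label under the feature's severity order.
#' @export
resolve_most_severe <- function(feature, labels) {
  stopifnot(inherits(feature, "feature_schema"))
  if (!length(labels)) stop_ctx("resolve_most_severe: empty label list")
  labels <- normalize_label(labels)
  bad <- setdiff(labels, feature$classes)
  if (length(bad))
    stop_ctx("feature '%s': unknown label '%s'", feature$feature_id, bad[1])
  subst <- labels[labels != NOT_PRESENT]
  if (!length(subst)) return(NOT_PRESENT)
  subst[which.max(match(subst, feature$severity))]
}

severity_rank <- function(feature, label) {
  # not_present ranks 0, below every substantive class
  ifelse(label == NOT_PRESENT, 0L, match(label, feature$severity))
}
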