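#' Synthetic labelled pathology-report corpora
#'
#' Clinical report corpora cannot be redistributed, so the package generates
#' synthetic ones with the statistical and stylistic structure the pipeline
#' must survive: right-skewed report lengths (log-normal word counts clipped
#' to the observed 7-3213 range, mean about 340 words), `"[redacted]"`
#' tokens from upstream de-identification, positively identifiable biomarker
#' mentions in varied surface forms (abbreviations, word forms, misspelled
#' variants), impossible-answer reports (feature absent, "has been
#' requested", or value redacted), and multi-mention reports whose ground
#' truth is the most clinically severe mentioned class. Every report carries
#' its ground-truth class per feature, so extraction, routing,
#' classification and the evaluation protocol are all testable end to end.
#'
#' @name synthetic-reports
NULL

# Filler vocabulary: deliberately free of every feature alias and class
# surface form, so filler text can never produce a spurious extraction and
# generated corpora are PII-free by construction.
filler_words <- c(
  "specimen", "received", "formalin", "fixed", "paraffin", "embedded",
  "sections", "were", "examined", "under", "light", "microscopy", "routine",
  "processing", "applied", "tissue", "sample", "block", "slides", "reviewed",
  "with", "clinical", "correlation", "advised", "discussed", "during",
  "multidisciplinary", "meeting", "further", "levels", "cut", "material",
  "submitted", "in", "entirety", "representative", "appearances", "described",
  "macroscopically", "unremarkable", "previously", "reported", "findings",
  "consistent", "overall", "morphology", "assessment")

mention_templates <- c("%s: %s.", "%s is %s.", "The %s result is %s.", "%s %s.")
requested_templates <- c("%s has been requested.", "Staining for %s has been requested.")

#' Synthetic corpus configuration
#'
#' Defaults emulate the study corpus: mean word count about 340 with range
#' 7-3213, half of the reports positively identifiable per feature, and a
#' mix of impossible-answer kinds.
#'
#' @param features Feature ids to embed (default: all registry features at
#'   generation time).
#' @param n_reports Number of reports.
#' @param positive_fraction Fraction of reports (exactly, per feature)
#'   carrying a positively identifiable mention.
#' @param style_noise In \[0,1\]: probability a mention uses a non-canonical
#'   surface form and sentence template.
#' @param redaction_rate Probability a sentence gains a `"[redacted]"` token.
#' @param impossible_kinds Named weights over `absent`, `requested`,
#'   `redacted_value` for impossible-answer reports.
#' @param multi_mention_rate Probability a positive report mentions the
#'   feature twice (ground truth = most severe mention).
#' @param length_log_mean,length_log_sd Log-normal word-count parameters;
#'   the default mean is `log(339.9) - length_log_sd^2/2`, so the expected
#'   word count matches the emulated corpus mean of 339.9.
#' @param length_range Clip range for word counts.
#' @param seed Integer seed; identical configurations generate identical
#'   corpora.
#' @export
synthetic_config <- function(features = NULL, n_reports = 100L,
                             positive_fraction = 0.5, style_noise = 0,
                             redaction_rate = 0.1,
                             impossible_kinds = c(absent = 0.5, requested = 0.25,
                                                  redacted_value = 0.25),
                             multi_mention_rate = 0.1,
                             length_log_sd = 0.8,
                             length_log_mean = log(339.9) - length_log_sd^2 / 2,
                             length_range = c(7L, 3213L),
                             seed = 1L) {
  stopifnot(n_reports >= 1, positive_fraction >= 0, positive_fraction <= 1,
            style_noise >= 0, style_noise <= 1,
            redaction_rate >= 0, redaction_rate <= 1,
            multi_mention_rate >= 0, multi_mention_rate <= 1,
            all(impossible_kinds >= 0), sum(impossible_kinds) > 0)
  list(features = features, n_reports = as.integer(n_reports),
       positive_fraction = positive_fraction, style_noise = style_noise,
       redaction_rate = redaction_rate,
       impossible_kinds = impossible_kinds / sum(impossible_kinds),
       multi_mention_rate = multi_mention_rate,
       length_log_mean = length_log_mean, length_log_sd = length_log_sd,
       length_range = length_range, seed = as.integer(seed))
}

pick_surface <- function(feature, class, style_noise) {
  forms <- surface_forms(feature, class)
  if (length(forms) > 1 && stats::runif(1) < style_noise)
    sample(forms[-1], 1) else forms[1]
}

pick_template <- function(templates, style_noise) {
  if (length(templates) > 1 && stats::runif(1) < style_noise)
    sample(templates[-1], 1) else templates[1]
}

mention_sentence <- function(feature, class, style_noise) {
  form <- pick_surface(feature, class, style_noise)
  alias <- feature$aliases[1]
  alias <- paste0(toupper(substr(alias, 1, 1)), substr(alias, 2, nchar(alias)))
  list(sentence = sprintf(pick_template(mention_templates, style_noise), alias, form),
       form = form)
}

#' Generate a labelled synthetic corpus
#'
#' @param config A [synthetic_config()].
#' @param registry A `schema_registry` (default [default_registry()]).
#' @return A list of labelled reports; each element has `report` (list with
#'   `report_id`, `text`), `labels` (named character vector feature ->
#'   ground-truth class), and `provenance` (named list of the surface forms
#'   actually inserted). The whole corpus carries class
#'   `synthetic_corpus`.
#' @export
generate_corpus <- function(config = synthetic_config(),
                            registry = default_registry()) {
  feats <- config$features %||% names(registry)
  missing <- setdiff(normalize_label(feats), names(registry))
  if (length(missing)) stop_ctx("unknown feature '%s'", missing[1])
  feats <- normalize_label(feats)
  n <- config$n_reports

  with_seed(config$seed, {
    # exact positive counts per feature, independently shuffled
    pos_flags <- lapply(feats, function(f) {
      k <- round(config$positive_fraction * n)
      sample(rep(c(TRUE, FALSE), c(k, n - k)))
    })
    names(pos_flags) <- feats

    wc_target <- pmin(pmax(round(stats::rlnorm(n, config$length_log_mean,
                                               config$length_log_sd)),
                           config$length_range[1]), config$length_range[2])

    corpus <- vector("list", n)
    for (i in seq_len(n)) {
      labels <- character(0)
      provenance <- list()
      mention_sents <- character(0)
      for (f in feats) {
        feature <- registry[[f]]
        if (pos_flags[[f]][i]) {
          cls <- setdiff(feature$classes, NOT_PRESENT)
          c1 <- sample(cls, 1)
          m1 <- mention_sentence(feature, c1, config$style_noise)
          sents <- m1$sentence
          forms <- stats::setNames(m1$form, c1)   # names: class each form realises
          truth <- c1
          if (length(cls) > 1 && stats::runif(1) < config$multi_mention_rate) {
            c2 <- sample(setdiff(cls, c1), 1)
            m2 <- mention_sentence(feature, c2, config$style_noise)
            sents <- c(sents, m2$sentence)
            forms <- c(forms, stats::setNames(m2$form, c2))
            truth <- resolve_most_severe(feature, c(c1, c2))
          }
          labels[f] <- truth
          provenance[[f]] <- forms
          mention_sents <- c(mention_sents, sents)
        } else {
          kind <- sample(names(config$impossible_kinds), 1,
                         prob = config$impossible_kinds)
          alias <- feature$aliases[1]
          alias <- paste0(toupper(substr(alias, 1, 1)),
                          substr(alias, 2, nchar(alias)))
          if (kind == "requested") {
            mention_sents <- c(mention_sents,
                               sprintf(sample(requested_templates, 1), alias))
          } else if (kind == "redacted_value") {
            mention_sents <- c(mention_sents, sprintf("%s: [redacted].", alias))
          }
          labels[f] <- NOT_PRESENT
          provenance[[f]] <- character(0)
        }
      }
      mention_words <- if (length(mention_sents))
        sum(vapply(strsplit(mention_sents, "[[:space:]]+"), length, 0L)) else 0L
      n_filler <- max(0L, wc_target[i] - mention_words)
      filler_sents <- character(0)
      if (n_filler > 0) {
        words <- sample(filler_words, n_filler, replace = TRUE)
        starts <- seq(1, n_filler, by = 8L)
        filler_sents <- vapply(starts, function(s) {
          chunk <- words[s:min(n_filler, s + 7L)]
          paste0(paste(chunk, collapse = " "), ".")
        }, "")
      }
      sents <- filler_sents
      for (ms in mention_sents) {
        pos <- sample.int(length(sents) + 1L, 1L)
        sents <- append(sents, ms, after = pos - 1L)
      }
      redact <- stats::runif(length(sents)) < config$redaction_rate
      sents[redact] <- paste(sents[redact], "[redacted]")
      corpus[[i]] <- list(
        report = list(report_id = sprintf("synth-%05d", i),
                      text = paste(sents, collapse = " ")),
        labels = labels,
        provenance = provenance
      )
    }
    structure(corpus, class = "synthetic_corpus", features = feats,
              config = config)
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  wc <- vapply(x, function(r)
    length(strsplit(r$report$text, "[[:space:]]+")[[1]]), 0L)
  cat(sprintf("<synthetic_corpus> %d reports, %d features, mean %.1f words\n",
              length(x), length(attr(x, "features")), mean(wc)))
  invisible(x)
}

#' Corpus accessors
#'
#' @param corpus A corpus from [generate_corpus()].
#' @return `corpus_reports()`: data frame `report_id`, `text`.
#'   `corpus_truth()`: data frame `report_id`, `feature_id`, `label`.
#' @export
corpus_reports <- function(corpus) {
  data.frame(report_id = vapply(corpus, function(r) r$report$report_id, ""),
             text = vapply(corpus, function(r) r$report$text, ""),
             stringsAsFactors = FALSE)
}

#' @rdname corpus_reports
#' @export
corpus_truth <- function(corpus) {
  rows <- lapply(corpus, function(r)
    data.frame(report_id = r$report$report_id,
               feature_id = names(r$labels), label = unname(r$labels),
               stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Build a balanced evaluation split for one feature
#'
#' Samples, without replacement, `n_pos` reports with a positively
#' identifiable mention of the feature and `n_neg` impossible-answer
#' reports — the balanced per-feature test-set design of the evaluation
#' protocol.
#'
#' @param corpus A corpus from [generate_corpus()].
#' @param feature_id Feature to split on.
#' @param n_pos,n_neg Reports of each kind (defaults 50/50).
#' @param seed Sampling seed.
#' @return A list of labelled reports (subset of `corpus`).
#' @export
build_eval_split <- function(corpus, feature_id, n_pos = 50L, n_neg = 50L,
                             seed = 1L) {
  feature_id <- normalize_label(feature_id)
  labels <- vapply(corpus, function(r) unname(r$labels[feature_id]), "")
  if (anyNA(labels)) stop_ctx("corpus has no labels for feature '%s'", feature_id)
  pos <- which(labels != NOT_PRESENT)
  neg <- which(labels == NOT_PRESENT)
  if (length(pos) < n_pos || length(neg) < n_neg)
    stop_ctx(paste0("insufficient reports for feature '%s': have %d positively ",
                    "identifiable (need %d) and %d impossible (need %d)"),
             feature_id, length(pos), n_pos, length(neg), n_neg)
  with_seed(seed, {
    take <- c(if (n_pos > 0) pos[sample.int(length(pos), n_pos)],
              if (n_neg > 0) neg[sample.int(length(neg), n_neg)])
    corpus[take[sample.int(length(take))]]
  })
}

#' Labelled classifier examples from the style lexicon
#'
#' Draws `k` surface-form texts per substantive class of a feature (the
#' canonical form always included first), seeded — the "5-10 annotated
#' examples per class" a user would supply for a real corpus.
#'
#' @param registry A `schema_registry`.
#' @param feature_id Feature id.
#' @param k_per_class Examples per class (>= 1).
#' @param seed Sampling seed.
#' @return Data frame with columns `text`, `label`.
#' @export
make_examples <- function(registry, feature_id, k_per_class = 5L, seed = 1L) {
  stopifnot(k_per_class >= 1)
  feature <- get_feature(registry, feature_id)
  classes <- setdiff(feature$classes, NOT_PRESENT)
  with_seed(seed, {
    rows <- lapply(classes, function(cl) {
      forms <- surface_forms(feature, cl)
      texts <- forms[1]
      if (k_per_class > 1)
        texts <- c(texts, sample(forms, k_per_class - 1L, replace = TRUE))
      data.frame(text = texts, label = cl, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
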