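#' Evaluation protocol
#'
#' Implements the scoring used to compare extraction pipelines: per-feature
#' accuracy over a closed-vocabulary confusion table with macro-averaged
#' precision/recall/F1, 95% confidence intervals across features from the
#' Student-t distribution, Cohen's kappa interrater agreement,
#' misclassification breakdowns by truth kind and by assigned kind, and the
#' adaptability learning-curve experiment over training-subset sizes.
#'
#' @name evaluation
NULL

#' Score predictions against ground truth for one feature
#'
#' Accuracy is the percentage of reports whose predicted class equals the
#' annotated class; precision, recall and F1 are macro-averaged over the
#' classes present in the truth.
#'
#' @param predictions Data frame with `report_id`, `predicted_class`.
#' @param truths Data frame with `report_id`, `label`.
#' @param feature A [feature_schema()] providing the closed vocabulary.
#' @return List with `confusion` (truth x predicted matrix over the
#'   vocabulary) and `metrics` (`accuracy` in percent, `macro_precision`,
#'   `macro_recall`, `macro_f1`).
#' @export
score <- function(predictions, truths, feature) {
  if (!nrow(predictions)) stop_ctx("empty prediction set")
  m <- match(truths$report_id, predictions$report_id)
  if (anyNA(m))
    stop_ctx("no prediction for report_id '%s'", truths$report_id[which(is.na(m))[1]])
  if (nrow(predictions) != nrow(truths))
    stop_ctx("predictions and truths differ in report count (%d vs %d)",
             nrow(predictions), nrow(truths))
  truth <- normalize_label(truths$label)
  pred <- normalize_label(predictions$predicted_class[m])
  vocab <- feature$classes
  bad <- setdiff(c(truth, pred), vocab)
  if (length(bad))
    stop_ctx("label '%s' outside vocabulary of feature '%s'", bad[1],
             feature$feature_id)
  conf <- table(factor(truth, levels = vocab), factor(pred, levels = vocab))
  conf <- unclass(conf)
  total <- sum(conf)
  acc <- 100 * sum(diag(conf)) / total
  present <- vocab[rowSums(conf) > 0]
  per_class <- vapply(present, function(cl) {
    tp <- conf[cl, cl]
    fp <- sum(conf[, cl]) - tp
    fn <- sum(conf[cl, ]) - tp
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(p, r, f)
  }, numeric(3))
  list(confusion = conf,
       metrics = list(accuracy = acc,
                      macro_precision = mean(per_class[1, ]),
                      macro_recall = mean(per_class[2, ]),
                      macro_f1 = mean(per_class[3, ])))
}

#' Student-t confidence interval from summary statistics
#'
#' The 95% interval `mean +/- t_{n-1, 0.975} * sd / sqrt(n)` used to
#' summarise a per-feature score vector by its mean, sample standard
#' deviation, and feature count.
#'
#' @param mean Mean score.
#' @param sd Sample standard deviation across features.
#' @param n Number of features (>= 2).
#' @return Numeric `c(lower, upper)` (unrounded; results are conventionally
#'   reported at two decimals).
#' @export
ci_from_summary <- function(mean, sd, n) {
  if (n < 2) stop_ctx("confidence interval needs n >= 2")
  if (sd < 0) stop_ctx("sd must be non-negative")
  half <- stats::qt(0.975, df = n - 1) * sd / sqrt(n)
  c(lower = mean - half, upper = mean + half)
}

#' Summarise per-feature scores with a t-interval
#'
#' @param scores Numeric vector of per-feature scores (length >= 2).
#' @return A `summary_ci` list: `mean`, `sd`, `n`, `lower`, `upper`.
#' @export
ci_across_features <- function(scores) {
  if (length(scores) < 2) stop_ctx("need at least two per-feature scores")
  m <- mean(scores); s <- stats::sd(scores)
  ci <- ci_from_summary(m, s, length(scores))
  structure(list(mean = m, sd = s, n = length(scores),
                 lower = unname(ci[1]), upper = unname(ci[2])),
            class = "summary_ci")
}

#' @export
print.summary_ci <- function(x, ...) {
  cat(sprintf("%.2f [%.2f, %.2f] (sd %.2f, n %d)\n",
              x$mean, x$lower, x$upper, x$sd, x$n))
  invisible(x)
}

#' Misclassification breakdown by truth kind and assigned kind
#'
#' Decomposes the errors two ways: how many truth-impossible
#' (`"not_present"`) reports were given a substantive class vs. how many
#' truth-positive reports were wrong, and how many errors were *assigned*
#' the impossible class vs. a substantive class. Both decompositions sum to
#' the total error count.
#'
#' @inheritParams score
#' @return List with `misclassified_impossible`, `misclassified_positive`,
#'   `assigned_impossible`, `assigned_positive`, `total_errors`.
#' @export
misclass_breakdown <- function(predictions, truths, feature) {
  m <- match(truths$report_id, predictions$report_id)
  if (anyNA(m))
    stop_ctx("no prediction for report_id '%s'", truths$report_id[which(is.na(m))[1]])
  truth <- normalize_label(truths$label)
  pred <- normalize_label(predictions$predicted_class[m])
  err <- truth != pred
  list(misclassified_impossible = sum(err & truth == NOT_PRESENT),
       misclassified_positive = sum(err & truth != NOT_PRESENT),
       assigned_impossible = sum(err & pred == NOT_PRESENT),
       assigned_positive = sum(err & pred != NOT_PRESENT),
       total_errors = sum(err))
}

#' Cohen's kappa interrater agreement
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' chance agreement `p_e = sum_c p_a(c) p_b(c)`. When `p_e = 1` (both
#' annotators constant on the same label) kappa is defined as 1 if the
#' vectors agree perfectly and 0 otherwise.
#'
#' @param labels_a,labels_b Equal-length label vectors (length >= 1).
#' @return List with `p_o`, `p_e`, `kappa`.
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop_ctx("label vectors differ in length (%d vs %d)",
             length(labels_a), length(labels_b))
  if (!length(labels_a)) stop_ctx("empty label vectors")
  a <- as.character(labels_a); b <- as.character(labels_b)
  p_o <- mean(a == b)
  lv <- union(a, b)
  p_e <- sum((table(factor(a, lv)) / length(a)) * (table(factor(b, lv)) / length(b)))
  p_e <- as.numeric(p_e)
  kappa <- if (1 - p_e < .Machine$double.eps) {
    if (p_o == 1) 1 else 0
  } else (p_o - p_e) / (1 - p_e)
  list(p_o = p_o, p_e = p_e, kappa = kappa)
}

#' Adaptability learning curve over training-subset sizes
#'
#' For each feature and permutation: a fixed balanced test split
#' (`n_pos`/`n_neg` reports) is drawn, the remaining reports form the
#' training pool, and nested training subsets of the configured sizes are
#' sampled. For each size, classifier examples are built from the subset's
#' positively identifiable reports (their inserted surface forms with the
#' ground-truth class), the classifier is refit, and accuracy is measured on
#' the fixed test split. Per size, per-feature accuracies (averaged over
#' permutations) are aggregated into a mean with a Student-t interval across
#' features.
#'
#' @param corpus A corpus from [generate_corpus()].
#' @param registry A `schema_registry`.
#' @param features Feature ids to evaluate.
#' @param sizes Training-subset sizes.
#' @param permutations Number of seeded test/train permutations.
#' @param pipeline_factory `function(examples, feature)` returning a fitted
#'   classifier model (or `NULL` when `examples` is empty). Default:
#'   prototype classifier on the hashing embedder.
#' @param backend Extractive backend (default [rule_based_backend()]).
#' @param config A [pipeline_config()].
#' @param n_pos,n_neg Test-split composition per feature.
#' @param seed Master seed for splits and subsets.
#' @return List with `results` (data frame: feature, size, permutation,
#'   accuracy) and `summary` (data frame per size: mean, sd, lower, upper).
#' @export
learning_curve <- function(corpus, registry, features,
                           sizes = c(5L, 10L, 20L, 50L, 100L),
                           permutations = 5L, pipeline_factory = NULL,
                           backend = rule_based_backend(),
                           config = pipeline_config(),
                           n_pos = 50L, n_neg = 50L, seed = 1L) {
  features <- normalize_label(features)
  if (is.null(pipeline_factory)) {
    embedder <- hashing_embedder()
    pipeline_factory <- function(examples, feature) {
      if (is.null(examples) || !nrow(examples)) return(NULL)
      fit_prototype(examples, embedder, feature)
    }
  }
  ids <- vapply(corpus, function(r) r$report$report_id, "")
  rows <- list()
  for (fi in seq_along(features)) {
    feature <- get_feature(registry, features[fi])
    for (p in seq_len(permutations)) {
      sp <- derive_seed(seed, fi * 1000L + p)
      test <- build_eval_split(corpus, feature$feature_id, n_pos, n_neg, seed = sp)
      test_ids <- vapply(test, function(r) r$report$report_id, "")
      pool <- corpus[!ids %in% test_ids]
      if (length(pool) < max(sizes))
        stop_ctx(paste0("corpus too small for feature '%s': training pool has ",
                        "%d reports, largest size needs %d"),
                 feature$feature_id, length(pool), max(sizes))
      pool <- with_seed(derive_seed(sp, 7L), pool[sample.int(length(pool))])
      test_reports <- lapply(test, `[[`, "report")
      truth <- data.frame(
        report_id = test_ids,
        label = vapply(test, function(r) unname(r$labels[feature$feature_id]), ""))
      for (s in sizes) {
        subset <- pool[seq_len(s)]   # nested: size-5 subset of size-10 ...
        ex <- do.call(rbind, lapply(subset, function(r) {
          lab <- unname(r$labels[feature$feature_id])
          forms <- r$provenance[[feature$feature_id]]
          if (is.na(lab) || lab == NOT_PRESENT || !length(forms)) return(NULL)
          # the annotated example is the mention realising the resolved
          # (most severe) class
          form <- if (!is.null(names(forms)) && lab %in% names(forms))
            forms[[lab]] else forms[[1]]
          data.frame(text = form, label = lab, stringsAsFactors = FALSE)
        }))
        model <- pipeline_factory(ex, feature)
        preds <- run_batch(test_reports, feature, backend, model, config)
        acc <- score(data.frame(report_id = preds$report_id,
                                predicted_class = preds$predicted_class),
                     truth, feature)$metrics$accuracy
        rows[[length(rows) + 1L]] <- data.frame(
          feature = feature$feature_id, size = s, permutation = p,
          accuracy = acc, stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(sort(unique(results$size)), function(s) {
    per_feature <- tapply(results$accuracy[results$size == s],
                          results$feature[results$size == s], mean)
    if (length(per_feature) < 2)
      return(data.frame(size = s, mean = mean(per_feature), sd = NA_real_,
                        lower = NA_real_, upper = NA_real_))
    ci <- ci_across_features(as.numeric(per_feature))
    data.frame(size = s, mean = ci$mean, sd = ci$sd,
               lower = ci$lower, upper = ci$upper)
  }))
  list(results = results, summary = summary)
}
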