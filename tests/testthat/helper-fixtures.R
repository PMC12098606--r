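# Shared fixtures and independent oracles. Everything here is built in code;
# no stored data.

REG <- default_registry()
EMB <- hashing_embedder()

`%||%` <- function(a, b) if (is.null(a)) b else a

# reports as run_pipeline wants them
as_reports <- function(split) lapply(split, `[[`, "report")

truth_frame <- function(split, feature_id) {
  data.frame(
    report_id = vapply(split, function(r) r$report$report_id, ""),
    label = vapply(split, function(r) unname(r$labels[feature_id]), ""),
    stringsAsFactors = FALSE)
}

# Independent brute-force prototype classifier: explicit pairwise cosines,
# explicit per-class max, argmax with first-in-class-order tie-break.
brute_prototype <- function(ex_vecs, ex_labels, classes, query) {
  sims <- vapply(ex_vecs, function(v) {
    sum(v * query) / (sqrt(sum(v^2)) * sqrt(sum(query^2)))
  }, numeric(1))
  class_scores <- vapply(classes, function(cl) max(sims[ex_labels == cl]),
                         numeric(1))
  best <- classes[1]; best_s <- class_scores[1]
  for (cl in classes) {
    if (class_scores[cl] > best_s + 1e-12) { best <- cl; best_s <- class_scores[cl] }
  }
  list(label = best, scores = class_scores)
}

# An embedder backed by a fixed table of vectors, for hand-built geometry.
table_embedder <- function(vectors) clinenrich:::lookup_embedder(vectors)

# Independent recount of accuracy / breakdown by explicit looping.
brute_recount <- function(truth, pred) {
  mi <- mp <- ai <- ap <- correct <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] == pred[i]) { correct <- correct + 1L; next }
    if (truth[i] == "not_present") mi <- mi + 1L else mp <- mp + 1L
    if (pred[i] == "not_present") ai <- ai + 1L else ap <- ap + 1L
  }
  list(accuracy = 100 * correct / length(truth),
       misclassified_impossible = mi, misclassified_positive = mp,
       assigned_impossible = ai, assigned_positive = ap)
}

# Map an extracted span text back to its class via the full surface lexicon.
lexicon_class <- function(feature, text) {
  vt <- clinenrich:::value_pattern_table(feature)
  vt$class[match(tolower(text), tolower(vt$form))]
}

# Small separable text clusters for contrastive tests (disjoint n-grams).
separable_examples <- function(k = 4) {
  data.frame(
    text = c(paste("alpha", c("one", "two", "three", "four")[seq_len(k)]),
             paste("zulu", c("nine", "eight", "seven", "six")[seq_len(k)])),
    label = rep(c("apple", "zebra"), each = k),
    stringsAsFactors = FALSE)
}
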