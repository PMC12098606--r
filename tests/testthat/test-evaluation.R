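toy_feature <- feature_schema("toy", "q?", classes = c("a", "b", "c"),
                              aliases = "toy")

pred_truth <- function(truth, pred) {
  ids <- paste0("r", seq_along(truth))
  list(pred = data.frame(report_id = ids, predicted_class = pred),
       truth = data.frame(report_id = ids, label = truth))
}

test_that("scoring reproduces hand-computed confusion metrics", {
  pt <- pred_truth(c("a", "a", "b"), c("a", "a", "b"))
  sc <- score(pt$pred, pt$truth, toy_feature)
  expect_equal(sc$metrics$accuracy, 100)
  expect_equal(sc$metrics$macro_f1, 1)

  # truth: 3 a (2 right, 1 -> b); 2 b (1 right, 1 -> a)
  pt <- pred_truth(c("a", "a", "a", "b", "b"), c("a", "a", "b", "b", "a"))
  sc <- score(pt$pred, pt$truth, toy_feature)
  expect_equal(sc$metrics$accuracy, 60)
  p_a <- 2 / 3; r_a <- 2 / 3; f_a <- 2 * p_a * r_a / (p_a + r_a)
  p_b <- 1 / 2; r_b <- 1 / 2; f_b <- 2 * p_b * r_b / (p_b + r_b)
  expect_equal(sc$metrics$macro_precision, mean(c(p_a, p_b)))
  expect_equal(sc$metrics$macro_recall, mean(c(r_a, r_b)))
  expect_equal(sc$metrics$macro_f1, mean(c(f_a, f_b)))

  expect_error(score(data.frame(report_id = character(), predicted_class = character()),
                     pt$truth, toy_feature), "empty prediction")
  expect_error(score(pt$pred[1:3, ], pt$truth, toy_feature), "no prediction")
})

test_that("the t-interval reproduces printed summary intervals at two decimals", {
  cases <- list(list(64.56, 10.81, c(59.18, 69.94)),
                list(96.61, 5.53, c(93.86, 99.36)),
                list(98.67, 1.08, c(98.13, 99.21)),
                list(90.94, 9.93, c(86.00, 95.88)))
  for (cs in cases)
    expect_equal(round(unname(ci_from_summary(cs[[1]], cs[[2]], 18)), 2), cs[[3]])
  expect_equal(unname(ci_from_summary(42.5, 0, 6)), c(42.5, 42.5))
  expect_error(ci_from_summary(50, 5, 1), "n >= 2")
})

test_that("per-feature aggregation matches its summary-statistic form", {
  ci <- ci_across_features(c(0, 100))
  expect_equal(ci$mean, 50)
  expect_equal(ci$sd, 70.71, tolerance = 1e-4)
  scores <- c(91.2, 88.4, 95.0, 99.1, 90.3)
  expect_equal(unlist(ci_across_features(scores)[c("lower", "upper")]),
               unname(ci_from_summary(mean(scores), sd(scores), length(scores))),
               ignore_attr = TRUE)
  same <- ci_across_features(rep(88, 18))
  expect_equal(same$lower, same$upper)
})

test_that("misclassification breakdowns reconcile and match brute-force recounts", {
  pt <- pred_truth(c("a", "a", "b"), c("a", "a", "b"))
  mb <- misclass_breakdown(pt$pred, pt$truth, toy_feature)
  expect_true(all(unlist(mb) == 0))

  pt <- pred_truth(c("a", "not_present"), c("not_present", "not_present"))
  mb <- misclass_breakdown(pt$pred, pt$truth, toy_feature)
  expect_equal(mb$misclassified_positive, 1L)
  expect_equal(mb$assigned_impossible, 1L)

  set.seed(55)
  vocab <- c("not_present", "a", "b", "c")
  for (i in 1:500) {
    n <- sample(5:20, 1)
    truth <- sample(vocab, n, replace = TRUE)
    pred <- sample(vocab, n, replace = TRUE)
    pt <- pred_truth(truth, pred)
    mb <- misclass_breakdown(pt$pred, pt$truth, toy_feature)
    want <- brute_recount(truth, pred)
    expect_equal(mb$misclassified_impossible, want$misclassified_impossible)
    expect_equal(mb$misclassified_positive, want$misclassified_positive)
    expect_equal(mb$assigned_impossible, want$assigned_impossible)
    expect_equal(mb$assigned_positive, want$assigned_positive)
    expect_equal(mb$misclassified_impossible + mb$misclassified_positive,
                 mb$total_errors)
    expect_equal(mb$assigned_impossible + mb$assigned_positive, mb$total_errors)
    sc <- score(pt$pred, pt$truth, toy_feature)
    expect_equal(sc$metrics$accuracy, want$accuracy)
    expect_equal(sum(sc$confusion) - sum(diag(sc$confusion)), mb$total_errors)
  }
})

test_that("Cohen's kappa follows its closed form and conventions", {
  expect_equal(cohens_kappa(c("x", "y", "x"), c("x", "y", "x"))$kappa, 1)
  expect_error(cohens_kappa(c("x"), c("x", "y")), "differ in length")

  # 2x2 table: 45 agree-positive, 15 agree-negative, 20+20 disagreements
  a <- c(rep("pos", 45), rep("neg", 15), rep("pos", 20), rep("neg", 20))
  b <- c(rep("pos", 45), rep("neg", 15), rep("neg", 20), rep("pos", 20))
  k <- cohens_kappa(a, b)
  p_o <- 60 / 100
  p_e <- (65 / 100) * (65 / 100) + (35 / 100) * (35 / 100)
  expect_equal(k$p_o, p_o)
  expect_equal(k$p_e, p_e)
  expect_equal(k$kappa, (p_o - p_e) / (1 - p_e))
  # symmetry
  expect_equal(cohens_kappa(b, a)$kappa, k$kappa)
  # constant identical raters: chance agreement 1, perfect observed agreement
  expect_equal(cohens_kappa(rep("z", 5), rep("z", 5))$kappa, 1)
  expect_equal(cohens_kappa(rep(c("z", "z"), 2), c("z", "w", "z", "z"))$kappa, 0)
  # independent raters drift to zero
  set.seed(99)
  expect_lt(abs(cohens_kappa(sample(c("u", "v"), 4000, replace = TRUE),
                             sample(c("u", "v"), 4000, replace = TRUE))$kappa), 0.05)
})

test_that("the learning curve runs at minimal scale and reproduces under a seed", {
  corpus <- generate_corpus(
    synthetic_config(features = c("cga", "egfr"), n_reports = 80, seed = 21), REG)
  lc <- learning_curve(corpus, REG, c("cga", "egfr"), sizes = c(5, 20),
                       permutations = 1, n_pos = 15, n_neg = 15, seed = 3)
  expect_equal(nrow(lc$results), 4L)     # 2 features x 2 sizes x 1 permutation
  expect_true(all(lc$results$accuracy >= 0 & lc$results$accuracy <= 100))
  lc2 <- learning_curve(corpus, REG, c("cga", "egfr"), sizes = c(5, 20),
                        permutations = 1, n_pos = 15, n_neg = 15, seed = 3)
  expect_identical(lc$results, lc2$results)
  expect_error(
    learning_curve(corpus, REG, "cga", sizes = c(500), permutations = 1,
                   n_pos = 15, n_neg = 15, seed = 3),
    "too small")
})
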