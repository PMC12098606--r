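test_that("prototype fitting keeps its bookkeeping contracts", {
  ex <- data.frame(text = c(paste("pos", 1:5), paste("neg", 1:5)),
                   label = rep(c("positive", "negative"), each = 5))
  m <- fit_prototype(ex, EMB)
  expect_equal(nrow(m$embeddings), 10L)
  expect_error(
    fit_prototype(data.frame(text = "x", label = "not_present"), EMB),
    "not_present")
  single <- fit_prototype(data.frame(text = "only", label = "solo"), EMB)
  expect_identical(classify_prototype(single, "anything")$label, "solo")
})

test_that("a stored example classifies to its own class with score 1", {
  ex <- data.frame(text = c("positive", "negative", "equivocal"),
                   label = c("positive", "negative", "equivocal"))
  m <- fit_prototype(ex, EMB, REG$alk)
  out <- classify_prototype(m, "positive")
  expect_identical(out$label, "positive")
  expect_equal(unname(out$scores["positive"]), 1, tolerance = 1e-12)
})

test_that("an orthogonal query falls to the first schema class at uniform confidence", {
  vecs <- list(a = c(1, 0, 0), b = c(0, 1, 0), q = c(0, 0, 1))
  m <- fit_prototype(data.frame(text = c("a", "b"), label = c("c1", "c2")),
                     table_embedder(vecs))
  out <- classify_prototype(m, "q")
  expect_identical(out$label, "c1")
  expect_equal(out$confidence, 0.5, tolerance = 1e-12)
})

test_that("prototype classification matches the brute-force oracle on random instances", {
  set.seed(101)
  for (rep in 1:1000) {
    d <- sample(2:6, 1); K <- sample(2:4, 1)
    classes <- paste0("k", seq_len(K))
    n_per <- sample(1:4, K, replace = TRUE)
    labels <- rep(classes, n_per)
    vecs <- lapply(seq_along(labels), function(i) stats::rnorm(d))
    names(vecs) <- paste0("ex", seq_along(labels))
    vecs$q <- stats::rnorm(d)
    emb <- table_embedder(vecs)
    m <- fit_prototype(data.frame(text = names(vecs)[seq_along(labels)],
                                  label = labels), emb)
    got <- classify_prototype(m, "q")
    unit <- function(v) v / sqrt(sum(v^2))
    want <- brute_prototype(lapply(vecs[seq_along(labels)], unit), labels,
                            classes, unit(vecs$q))
    expect_identical(got$label, want$label)
    expect_equal(unname(got$scores), unname(want$scores), tolerance = 1e-9)
  }
})

test_that("pair sampling counts, reproduces, and refuses one class", {
  ex <- data.frame(text = paste0("t", 1:4), label = rep(c("a", "b"), each = 2))
  p1 <- sample_pairs(ex, R = 2, seed = 5)
  expect_equal(nrow(p1), 8L)            # 1 positive + 1 negative per example
  expect_identical(p1, sample_pairs(ex, R = 2, seed = 5))
  expect_false(identical(p1, sample_pairs(ex, R = 2, seed = 6)))
  expect_error(sample_pairs(data.frame(text = c("x", "y"), label = c("a", "a"))),
               "two classes")
  lop <- data.frame(text = c("x", "y", "z"), label = c("a", "a", "b"))
  expect_warning(sample_pairs(lop, R = 2, seed = 1), "single example")
})

test_that("contrastive fitting separates toy clusters and is seed-deterministic", {
  ex <- separable_examples()
  m <- fit_contrastive(ex, EMB, config = contrastive_config(seed = 3))
  preds <- predict(m, ex$text)
  expect_identical(preds$label, ex$label)            # 100% training accuracy
  expect_lt(tail(m$loss_history, 1), m$loss_history[1])  # pair loss decreased
  p <- classify_fewshot(m, "alpha five")
  expect_equal(sum(p$probs), 1, tolerance = 1e-9)
  m2 <- fit_contrastive(ex, EMB, config = contrastive_config(seed = 3))
  expect_identical(m$head$weights, m2$head$weights)
  expect_identical(m$W, m2$W)
})

test_that("zero refinement epochs reduce the model to a head on base embeddings", {
  ex <- separable_examples(k = 2)
  m <- fit_contrastive(ex, EMB, config = contrastive_config(epochs = 0, seed = 1))
  expect_identical(m$W, diag(EMB$dim))
  expect_length(m$loss_history, 0L)
  expect_identical(predict(m, ex$text)$label, ex$label)
})

test_that("schema class order breaks classifier ties", {
  # two classes with identical example embeddings: every query ties
  vecs <- list(e1 = c(1, 0), e2 = c(1, 0), q = c(0.5, 0.5))
  m <- fit_prototype(data.frame(text = c("e1", "e2"), label = c("c1", "c2")),
                     table_embedder(vecs))
  expect_identical(classify_prototype(m, "q")$label, "c1")
})
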