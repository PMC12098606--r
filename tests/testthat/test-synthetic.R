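test_that("corpus generation is seeded and respects configuration", {
  cfg <- synthetic_config(features = c("p53", "grade"), n_reports = 15, seed = 1)
  c1 <- generate_corpus(cfg, REG)
  c2 <- generate_corpus(cfg, REG)
  expect_identical(corpus_reports(c1), corpus_reports(c2))
  expect_identical(corpus_truth(c1), corpus_truth(c2))

  all_pos <- generate_corpus(
    synthetic_config(features = "p53", n_reports = 12, positive_fraction = 1,
                     seed = 2), REG)
  expect_true(all(corpus_truth(all_pos)$label != "not_present"))

  expect_error(generate_corpus(synthetic_config(features = "martian"), REG),
               "unknown feature 'martian'")
})

test_that("word counts follow the configured length model", {
  corpus <- generate_corpus(
    synthetic_config(features = "p53", n_reports = 3000, seed = 13), REG)
  wc <- vapply(corpus, function(r)
    length(strsplit(r$report$text, "[[:space:]]+")[[1]]), 0L)
  expect_lt(abs(mean(wc) - 339.9) / 339.9, 0.10)
  expect_gte(min(wc), 7L)
})

test_that("positive reports re-parse to their ground-truth class at zero noise", {
  corpus <- generate_corpus(
    synthetic_config(features = c("figo", "mmr"), n_reports = 60, style_noise = 0,
                     multi_mention_rate = 0.3, seed = 3), REG)
  for (f in c("figo", "mmr")) {
    for (r in corpus) {
      if (r$labels[f] == "not_present") next
      s <- rule_based_extract(r$report$text, REG[[f]])
      cands <- attr(s, "candidates")
      classes <- vapply(cands, function(cc) lexicon_class(REG[[f]], cc$text), "")
      expect_identical(resolve_most_severe(REG[[f]], classes), unname(r$labels[f]))
    }
  }
})

test_that("evaluation splits have the requested composition", {
  corpus <- generate_corpus(
    synthetic_config(features = "p53", n_reports = 60, seed = 4), REG)
  split <- build_eval_split(corpus, "p53", n_pos = 20, n_neg = 20, seed = 5)
  labs <- vapply(split, function(r) unname(r$labels["p53"]), "")
  expect_length(labs, 40L)
  expect_equal(sum(labs != "not_present"), 20L)
  neg_only <- build_eval_split(corpus, "p53", n_pos = 0, n_neg = 10, seed = 5)
  expect_true(all(vapply(neg_only, function(r) r$labels["p53"], "") == "not_present"))
  expect_error(build_eval_split(corpus, "p53", n_pos = 50, n_neg = 50, seed = 5),
               "insufficient reports")
})

test_that("lexicon example sets count and reproduce", {
  expect_equal(nrow(make_examples(REG, "p53", 5, seed = 1)), 10L)
  expect_equal(nrow(make_examples(REG, "figo", 2, seed = 1)), 28L)
  expect_identical(make_examples(REG, "her2", 4, seed = 9),
                   make_examples(REG, "her2", 4, seed = 9))
  ex <- make_examples(REG, "grade", 3, seed = 2)
  expect_true(all(ex$label %in% setdiff(REG$grade$classes, "not_present")))
})

test_that("generated text stays inside the template vocabulary (PII-free)", {
  corpus <- generate_corpus(
    synthetic_config(features = "her2", n_reports = 25, style_noise = 1, seed = 6),
    REG)
  allowed <- c(clinenrich:::filler_words, "[redacted]")
  feature_words <- unique(unlist(c(
    strsplit(REG$her2$aliases, " "),
    lapply(setdiff(REG$her2$classes, "not_present"),
           function(cl) strsplit(surface_forms(REG$her2, cl), " ")),
    strsplit(c("is", "the", "result", "has", "been", "requested", "staining", "for"), " "))))
  for (r in corpus) {
    words <- strsplit(tolower(gsub("[.:]", "", r$report$text)), "[[:space:]]+")[[1]]
    expect_true(all(words %in% c(allowed, feature_words)),
                info = paste("stray words:",
                             paste(setdiff(words, c(allowed, feature_words)),
                                   collapse = ", ")))
  }
})
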