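test_that("packaged registry carries the expected vocabularies", {
  expect_s3_class(REG, "schema_registry")
  expect_length(REG, 23L)
  expect_setequal(REG$her2$classes,
                  c("positive", "equivocal", "negative", "1", "2", "3", "not_present"))
  expect_setequal(REG$figo$classes,
                  c("1", "1a", "1b", "1c", "2", "2a", "2b", "3", "3a", "3b",
                    "3c", "4", "4a", "4b", "not_present"))
  expect_setequal(REG$tnm_m$classes, c("x", "0", "1", "1a", "1b", "1c", "not_present"))
  # bounded numeric families alongside categorical classes
  expect_true(all(as.character(0:100) %in% REG$blast_cell_percentage$classes))
  expect_true(all(c("no_excess", "an_excess") %in% REG$blast_cell_percentage$classes))
  expect_true(all(as.character(0:8) %in% REG$er$classes))
})

test_that("every packaged vocabulary contains not_present with minimal severity", {
  for (f in REG) {
    expect_true("not_present" %in% f$classes)
    expect_false("not_present" %in% f$severity)
    expect_setequal(f$severity, setdiff(f$classes, "not_present"))
    others <- setdiff(f$classes, "not_present")
    expect_identical(resolve_most_severe(f, c("not_present", others[1])), others[1])
  }
})

test_that("load_registry validates its input", {
  expect_length(load_registry(list(features = list())), 0L)
  dup <- list(features = list(
    list(feature_id = "p53", question = "q", classes = c("positive", "negative"),
         aliases = "p53"),
    list(feature_id = "p53", question = "q", classes = c("a", "b"), aliases = "p53")))
  expect_error(load_registry(dup), "duplicate feature_id 'p53'")
  expect_error(
    feature_schema("g", "q", classes = c("a", "b", "a"), aliases = "g"),
    "duplicate class")
  expect_error(
    feature_schema("g", "q", classes = c("a", "b"), aliases = "g",
                   severity = c("a", "c")),
    "not a permutation")
  # not_present injected and labels canonicalised
  f <- feature_schema("g", "q", classes = c("Positive", "NEGATIVE"), aliases = "g")
  expect_setequal(f$classes, c("not_present", "positive", "negative"))
})

test_that("registry config round-trips through a file", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "features:",
    "- feature_id: demo",
    "  question: What is the demo status?",
    "  aliases: [demo]",
    "  classes: [low, high]",
    "  severity: [low, high]"), path)
  reg <- load_registry(path)
  expect_identical(names(reg), "demo")
  expect_identical(resolve_most_severe(reg$demo, c("low", "high")), "high")
})

test_that("resolve_most_severe matches a brute-force maximum and is order independent", {
  # brute force: scan the packaged severity list from the top
  brute_max <- function(f, labels) {
    subst <- setdiff(labels, "not_present")
    if (!length(subst)) return("not_present")
    for (cl in rev(f$severity)) if (cl %in% subst) return(cl)
  }
  expect_identical(resolve_most_severe(REG$figo, c("1a", "3a")), "3a")
  expect_identical(resolve_most_severe(REG$figo, c("1a", "3a")),
                   brute_max(REG$figo, c("1a", "3a")))
  expect_identical(resolve_most_severe(REG$tnm_n, "x"), "x")
  expect_error(resolve_most_severe(REG$figo, c("1a", "banana")), "unknown label")

  set.seed(41)
  for (rep in 1:50) {
    f <- REG[[sample(length(REG), 1)]]
    labs <- sample(f$classes, sample(1:4, 1), replace = TRUE)
    res <- resolve_most_severe(f, labs)
    expect_identical(res, brute_max(f, labs))
    expect_identical(res, resolve_most_severe(f, sample(labs)))   # permutation
    expect_identical(res, resolve_most_severe(f, c(labs, res)))   # idempotent
  }
})
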