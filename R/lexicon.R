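# Surface-form lexicon: how each class of each feature is written in free
# text. The first form is canonical (used at style_noise = 0); later forms
# are the stylistic variants observed in pathology reporting (abbreviations,
# word forms of numeric grades, a deterministic one-typo misspelling). The
# same lexicon drives mention insertion in the synthetic generator, value
# scanning in the rule-based extractive backend, and classifier example
# construction, which is what makes label-consistency checkable end to end.

# Deterministic single-typo variant: swap the two middle characters.
swap_typo <- function(word) {
  n <- nchar(word)
  if (n < 5) return(character(0))
  i <- n %/% 2
  paste0(substr(word, 1, i - 1), substr(word, i + 1, i + 1),
         substr(word, i, i), substr(word, i + 2, n))
}

generic_variants <- list(
  positive  = c("positive", "pos", "+ve", "strongly positive"),
  negative  = c("negative", "neg", "weakly negative"),
  equivocal = c("equivocal", "borderline"),
  present   = c("present", "identified", "evident"),
  absent    = c("absent", "lost"),
  intact    = c("intact", "preserved", "retained"),
  deficient = c("deficient", "loss"),
  no_excess = c("no excess", "not in excess"),
  an_excess = c("an excess", "excess"),
  x         = c("x")
)

feature_specific_variants <- list(
  p53 = list(
    positive = c("positive", "aberrant", "mutant", "pos"),
    negative = c("negative", "wild-type", "wild type", "neg")
  ),
  grade = list(
    "1" = c("1", "g1", "low grade"),
    "2" = c("2", "g2", "intermediate grade"),
    "3" = c("3", "g3", "high grade"),
    "4" = c("4", "g4")
  )
)

#' Surface forms of one class of a feature
#'
#' Returns the written forms a class takes in report text, canonical form
#' first. Stage-like and numeric classes are written as their label; word
#' classes carry abbreviation, phrase and misspelling variants.
#'
#' @param feature A [feature_schema()].
#' @param class A class label from the feature's vocabulary
#'   (not `"not_present"`).
#' @return Character vector of surface forms, canonical first.
#' @export
surface_forms <- function(feature, class) {
  class <- normalize_label(class)
  if (class == NOT_PRESENT)
    stop_ctx("not_present has no surface form; it encodes absence")
  if (!class %in% feature$classes)
    stop_ctx("feature '%s': unknown class '%s'", feature$feature_id, class)
  spec_list <- feature_specific_variants[[feature$feature_id]]
  forms <- if (!is.null(spec_list) && !is.null(spec_list[[class]])) {
    spec_list[[class]]
  } else if (!is.null(generic_variants[[class]])) {
    generic_variants[[class]]
  } else {
    # numeric / stage-like classes: the label itself, spelled with spaces
    gsub("_", " ", class)
  }
  canon <- forms[1]
  unique(c(forms, swap_typo(canon)))
}

# All (class, form) value patterns of a feature, one row per surface form.
value_pattern_table <- function(feature) {
  classes <- setdiff(feature$classes, NOT_PRESENT)
  rows <- lapply(classes, function(cl) {
    data.frame(class = cl, form = surface_forms(feature, cl),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
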