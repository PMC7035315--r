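#' Classify functional impact of annotated SNPs
#'
#' Maps annotation-tool impact strings onto the four canonical categories:
#' `HIGH` (e.g. stop-gain, frameshift), `MODERATE` (e.g. missense),
#' `LOW` (e.g. synonymous) and `MODIFIER` (everything outside coding
#' impact, used as the near-neutral reference class). Labels are
#' canonicalized (case, surrounding whitespace) before matching; anything
#' else is rejected.
#'
#' @param x character vector of category labels.
#' @return factor with levels `HIGH`, `MODERATE`, `LOW`, `MODIFIER`.
#'   Unrecognized labels raise an error naming the offending labels.
#' @examples
#' classify_impact(c("high", "MODIFIER", " low "))
#' @export
classify_impact <- function(x) {
  lab <- stringr::str_to_upper(stringr::str_trim(as.character(x)))
  levels <- c("HIGH", "MODERATE", "LOW", "MODIFIER")
  bad <- unique(lab[!lab %in% levels & !is.na(lab)])
  if (length(bad)) {
    abort(paste0("unrecognized impact label(s): ",
                 paste(bad, collapse = ", ")))
  }
  factor(lab, levels = levels)
}

#' Classify phylogenetic-conservation scores
#'
#' GERP rejected-substitution scores are binned at -2, 2, 4 and 6:
#' scores at or below -2 are `EXCLUDED` (low-confidence regions), `(-2, 2]`
#' is `NEUTRAL` (neutral or near neutral), `(2, 4]` `MODERATE`, `(4, 6]`
#' `LARGE` and above 6 `EXTREME`. For phyloP a site is conserved iff its
#' score exceeds 1; for phastCons iff the score equals 1, the maximum
#' attainable value. Missing scores are `EXCLUDED` (GERP) or
#' not conserved, with a count of missing values attached.
#'
#' @param score numeric score vector.
#' @param source `"GERP"`, `"PHYLOP"` or `"PHASTCONS"`.
#' @return For GERP, a factor with levels `EXCLUDED`, `NEUTRAL`,
#'   `MODERATE`, `LARGE`, `EXTREME`; for phyloP/phastCons a logical
#'   `conserved` vector. Attribute `n_missing` counts missing scores.
#' @examples
#' classify_conservation(c(1, 5, -2.5), "GERP")
#' @export
classify_conservation <- function(score, source = c("GERP", "PHYLOP", "PHASTCONS")) {
  source <- match.arg(toupper(source), c("GERP", "PHYLOP", "PHASTCONS"))
  n_missing <- sum(is.na(score))
  out <- switch(
    source,
    GERP = cut(score, breaks = c(-Inf, -2, 2, 4, 6, Inf),
               labels = c("EXCLUDED", "NEUTRAL", "MODERATE", "LARGE", "EXTREME"),
               right = TRUE),
    PHYLOP = !is.na(score) & score > 1,
    PHASTCONS = !is.na(score) & score == 1
  )
  if (source == "GERP") {
    out[is.na(score)] <- "EXCLUDED"
  }
  attr(out, "n_missing") <- n_missing
  out
}
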