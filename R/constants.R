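#' Fixed vocabularies used throughout the package
#'
#' `diseaseCategories()` returns the five major cause-of-death categories in
#' their canonical order (the order of all confusion-matrix rows and columns);
#' `coincidenceLevels()` the five ICD-10 code-coincidence levels from weakest
#' to strongest; `certaintyLevels()` the five diagnostic-certainty levels from
#' weakest to strongest.
#'
#' @return A character vector of level names.
#' @examples
#' diseaseCategories()
#' coincidenceLevels()
#' @export
diseaseCategories <- function() {
  c("infectious_diseases", "malignant_tumors", "congenital_malformations",
    "other_diseases", "nonconclusive")
}

#' @rdname diseaseCategories
#' @export
coincidenceLevels <- function() {
  c("none", "low", "moderate", "almost_perfect", "perfect")
}

#' @rdname diseaseCategories
#' @export
certaintyLevels <- function() {
  c("no_diagnosis", "low", "moderate", "high", "very_high")
}

#' Sentinel for a nonconclusive verdict
#'
#' A verdict with no attributable cause of death carries this sentinel in
#' place of an ICD-10 code. A verdict is nonconclusive if and only if its
#' diagnostic certainty is `"no_diagnosis"`.
#'
#' @return The sentinel string.
#' @export
nonconclusiveCode <- function() "NONCONCLUSIVE"

# internal: ordered-factor builders
.asCategory <- function(x) factor(x, levels = diseaseCategories())
.asCoincidence <- function(x) factor(x, levels = coincidenceLevels(), ordered = TRUE)
.asCertainty <- function(x) factor(x, levels = certaintyLevels(), ordered = TRUE)
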