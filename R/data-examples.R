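#' Packaged example data
#'
#' The package ships a synthetic 54-case example series of paired MIA/CDA
#' verdicts (`inst/extdata/mia_cda_synthetic_54.csv`) emulating a pediatric
#' validation study: 42 infectious, 7 malignant-tumor, 2 congenital and 3
#' other-disease deaths by CDA, with the MIA nonconclusive in 2. The per-case
#' codes are synthetic but the series reproduces the cross-tabulation of
#' [exampleConfusionMatrix()] and the coincidence counts of
#' [exampleCoincidenceCounts()] exactly, so the whole pipeline can be
#' exercised end to end without external data.
#'
#' `exampleCasesPath()` returns the CSV path; `exampleCases()` reads it with
#' [readCases()].
#'
#' @param ... passed on to [readCases()].
#' @return `exampleCasesPath()`: a path; `exampleCases()`: a
#'   [CaseSet-class].
#' @examples
#' evaluateCases(exampleCases())$kappa$estimate
#' @export
exampleCasesPath <- function() {
  system.file("extdata", "mia_cda_synthetic_54.csv", package = "CoDagree",
              mustWork = TRUE)
}

#' @rdname exampleCasesPath
#' @export
exampleCases <- function(...) readCases(exampleCasesPath(), ...)

#' @rdname exampleCasesPath
#' @export
exampleConfusionMatrix <- function() {
  path <- system.file("extdata", "example_confusion.tsv",
                      package = "CoDagree", mustWork = TRUE)
  d <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  ConfusionMatrix(as.matrix(d), categories = diseaseCategories())
}

#' @rdname exampleCasesPath
#' @export
exampleCoincidenceCounts <- function() {
  path <- system.file("extdata", "example_coincidence.tsv",
                      package = "CoDagree", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
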