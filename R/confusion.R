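#' Construct a confusion matrix directly
#'
#' @param counts K x K numeric matrix of counts, rows = MIA categories,
#'   columns = CDA categories. Dimnames, when present, must match
#'   `categories`.
#' @param categories category labels (default the five
#'   [diseaseCategories()]).
#' @return A [ConfusionMatrix-class].
#' @examples
#' ConfusionMatrix(diag(3), categories = c("a", "b", "c"))
#' @export
ConfusionMatrix <- function(counts, categories = diseaseCategories()) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(MIA = categories, CDA = categories)
  new("ConfusionMatrix", counts = counts, categories = categories)
}

#' @describeIn ConfusionMatrix-class the count matrix (rows = MIA,
#'   columns = CDA).
#' @param x a `ConfusionMatrix`.
#' @export
setMethod("confusionCounts", "ConfusionMatrix", function(x) x@counts)

#' @describeIn ConfusionMatrix-class the category labels.
#' @export
setMethod("categoryLabels", "ConfusionMatrix", function(x) x@categories)

#' @describeIn ConfusionMatrix-class total number of paired cases.
#' @export
setMethod("totalCases", "ConfusionMatrix", function(x) sum(x@counts))

setMethod("show", "ConfusionMatrix", function(object) {
  m <- object@counts
  cat(sprintf("ConfusionMatrix: %d cases, %d categories (rows MIA, cols CDA)\n",
              sum(m), length(object@categories)))
  print(cbind(m, Total = rowSums(m)))
  cat("Col totals:", colSums(m), "| diagonal:", sum(diag(m)), "\n")
})

#' Cross-tabulate paired verdicts into a confusion matrix
#'
#' Categorizes each arm's main cause of death with [categorizeCode()] and
#' counts cases in the fixed 5 x 5 category grid, MIA categories in rows and
#' CDA (gold standard) categories in columns. Each case contributes exactly
#' one count, so the matrix total equals the number of cases.
#'
#' @param cases a [CaseSet-class].
#' @param map a [CategoryMap-class].
#' @param table a [BlockTable-class].
#' @param ... unused.
#' @return A [ConfusionMatrix-class].
#' @examples
#' buildConfusionMatrix(readCases(exampleCasesPath()))
#' @export
setMethod("buildConfusionMatrix",
          signature("CaseSet", "CategoryMap", "BlockTable"),
  function(cases, map, table, ...) {
    d <- cases@data
    if (nrow(d) == 0L) stop("no cases to tabulate", call. = FALSE)
    mia <- categorizeCode(d$mia_code, map, table)
    cda <- categorizeCode(d$cda_code, map, table)
    counts <- table(MIA = mia, CDA = cda)
    ConfusionMatrix(unclass(counts), categories = diseaseCategories())
  })

#' @rdname buildConfusionMatrix-CaseSet-CategoryMap-BlockTable-method
#' @export
setMethod("buildConfusionMatrix",
          signature("CaseSet", "missing", "missing"),
  function(cases, map, table, ...) {
    buildConfusionMatrix(cases, defaultCategoryMap(), defaultBlockTable(), ...)
  })
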