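#' Tabulate ICD-10 code coincidence for category-concordant cases
#'
#' For the cases in which the two arms agree on the disease category, computes
#' the per-case ICD-10 [codeCoincidence()] level and tabulates it by category
#' and overall. Category-discordant cases are excluded from the denominator,
#' which therefore equals the confusion-matrix diagonal sum. Perfect and
#' almost-perfect are reported separately and merged. A concordant pair of
#' nonconclusive verdicts (both the sentinel, hence identical) counts as
#' perfect.
#'
#' @param cases a [CaseSet-class].
#' @param map a [CategoryMap-class].
#' @param table a [BlockTable-class].
#' @param ... unused.
#' @return data.frame with one row per represented category plus an
#'   `"overall"` row: columns `category`, `n`, `perfect`, `almost_perfect`,
#'   `perfect_or_almost`, `moderate`, `low`, `none`.
#' @examples
#' coincidenceTable(readCases(exampleCasesPath()))
#' @export
setMethod("coincidenceTable", signature("CaseSet", "CategoryMap", "BlockTable"),
  function(cases, map, table, ...) {
    d <- cases@data
    if (nrow(d) == 0L) stop("no cases to tabulate", call. = FALSE)
    mia <- categorizeCode(d$mia_code, map, table)
    cda <- categorizeCode(d$cda_code, map, table)
    conc <- as.character(mia) == as.character(cda)
    d <- d[conc, , drop = FALSE]
    cat <- as.character(cda)[conc]
    lvl <- rep(NA_character_, nrow(d))
    sentinel <- d$mia_code == nonconclusiveCode() &
      d$cda_code == nonconclusiveCode()
    lvl[sentinel] <- "perfect"
    if (any(!sentinel)) {
      lvl[!sentinel] <- as.character(codeCoincidence(
        parseIcd10(d$mia_code[!sentinel]), parseIcd10(d$cda_code[!sentinel]),
        table))
    }
    tallyOne <- function(category, levels) {
      counts <- table(factor(levels, levels = coincidenceLevels()))
      data.frame(category = category, n = length(levels),
                 perfect = as.integer(counts[["perfect"]]),
                 almost_perfect = as.integer(counts[["almost_perfect"]]),
                 perfect_or_almost = as.integer(counts[["perfect"]] +
                                                counts[["almost_perfect"]]),
                 moderate = as.integer(counts[["moderate"]]),
                 low = as.integer(counts[["low"]]),
                 none = as.integer(counts[["none"]]),
                 stringsAsFactors = FALSE)
    }
    present <- diseaseCategories()[diseaseCategories() %in% cat]
    rows <- lapply(present, function(cc) tallyOne(cc, lvl[cat == cc]))
    out <- rbind(tallyOne("overall", lvl), do.call(rbind, rows))
    rownames(out) <- NULL
    out
  })

#' @rdname coincidenceTable-CaseSet-CategoryMap-BlockTable-method
#' @export
setMethod("coincidenceTable", signature("CaseSet", "missing", "missing"),
  function(cases, map, table, ...) {
    coincidenceTable(cases, defaultCategoryMap(), defaultBlockTable(), ...)
  })
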