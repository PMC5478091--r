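#' Run the full concordance evaluation
#'
#' Builds the confusion matrix from a [CaseSet-class], computes Cohen's kappa
#' (both standard errors), overall agreement, per-category diagnostic
#' accuracy, and the ICD-10 coincidence tabulation, and returns everything as
#' one report list. Write it with [writeReportJson()] or render it for humans
#' with [renderReport()].
#'
#' @param cases a [CaseSet-class].
#' @param map a [CategoryMap-class].
#' @param table a [BlockTable-class].
#' @param level confidence level for all intervals.
#' @param minCertainty optional minimum certainty level (one of
#'   [certaintyLevels()]); cases in which either arm falls below it are
#'   dropped before analysis.
#' @param ... unused.
#' @return list with elements `n_cases`, `confusion`, `kappa`,
#'   `overall_agreement`, `per_category`, `coincidence`.
#' @examples
#' rep <- evaluateCases(readCases(exampleCasesPath()))
#' rep$kappa$estimate
#' @export
setMethod("evaluateCases", "CaseSet",
  function(cases, map = defaultCategoryMap(), table = defaultBlockTable(),
           level = 0.95, minCertainty = NULL, ...) {
    if (!is.null(minCertainty)) {
      stopifnot(minCertainty %in% certaintyLevels())
      d <- cases@data
      keep <- .asCertainty(d$mia_certainty) >= minCertainty &
        .asCertainty(d$cda_certainty) >= minCertainty
      cases <- new("CaseSet", data = d[keep, , drop = FALSE])
      if (length(cases) == 0L)
        stop("no cases remain after the certainty filter", call. = FALSE)
    }
    cm <- buildConfusionMatrix(cases, map, table)
    kp <- cohenKappa(cm, level = level)
    oa <- overallAgreement(cm, level = level)
    acc <- categoryAccuracy(cm, level = level)
    coin <- coincidenceTable(cases, map, table)
    list(
      n_cases = length(cases),
      confusion = list(categories = cm@categories,
                       counts = unname(cm@counts),
                       row_totals = unname(rowSums(cm@counts)),
                       col_totals = unname(colSums(cm@counts)),
                       n = sum(cm@counts)),
      kappa = list(estimate = kp@kappa, p_observed = kp@pObserved,
                   p_expected = kp@pExpected, se_null = kp@seNull,
                   se_alt = kp@seAlt, ci_low = kp@ciLow, ci_high = kp@ciHigh,
                   level = kp@level, interpretation = kp@interpretation),
      overall_agreement = oa,
      per_category = acc,
      coincidence = coin)
  })

#' Write an evaluation report as JSON
#'
#' Machine-readable form of an [evaluateCases()] report; numbers are written
#' at full precision.
#'
#' @param report list from [evaluateCases()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReportJson <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  invisible(path)
}

#' Render an evaluation report as text
#'
#' Human-readable rendering of an [evaluateCases()] report: the confusion
#' matrix with marginals, the kappa block, and the accuracy and coincidence
#' tables. Display rounding follows the field's conventions (percentages to
#' 0 dp, kappa to 2 dp, standard errors to 4 dp); full precision lives in the
#' JSON report.
#'
#' @param report list from [evaluateCases()].
#' @return character vector of lines, invisibly; printed when `print = TRUE`.
#' @param print logical, cat the lines to the console.
#' @export
renderReport <- function(report, print = TRUE) {
  pct <- function(x) ifelse(is.na(x), "N/A", sprintf("%.0f", 100 * x))
  ci <- function(lo, hi) ifelse(is.na(lo), "",
                                sprintf(" (%s, %s)", pct(lo), pct(hi)))
  lines <- character(0)
  add <- function(...) lines <<- c(lines, sprintf(...))

  cf <- report$confusion
  add("Concordance of cause-of-death categorization (rows MIA, cols CDA)")
  wide <- max(nchar(cf$categories)) + 2
  add(paste0(formatC("", width = wide),
             paste(formatC(abbreviate(cf$categories, 8), width = 9),
                   collapse = ""), formatC("Total", width = 9)))
  for (i in seq_along(cf$categories)) {
    add(paste0(formatC(cf$categories[i], width = wide, flag = "-"),
               paste(formatC(cf$counts[i, ], width = 9), collapse = ""),
               formatC(cf$row_totals[i], width = 9)))
  }
  add(paste0(formatC("Total", width = wide, flag = "-"),
             paste(formatC(cf$col_totals, width = 9), collapse = ""),
             formatC(cf$n, width = 9)))

  kp <- report$kappa
  add("")
  add("Kappa: %.2f (standard error %.4f; %d%% CI %.2f-%.2f) - %s concordance",
      kp$estimate, kp$se_null, round(100 * kp$level), kp$ci_low, kp$ci_high,
      kp$interpretation)
  add("  (CI from the large-sample SE %.4f; the quoted SE is the null SE)",
      kp$se_alt)
  oa <- report$overall_agreement
  add("Overall agreement: %d/%d = %s%% (%s, %s)", oa$agree, oa$n,
      pct(oa$proportion), pct(oa$ci_low), pct(oa$ci_high))

  add("")
  add("Diagnostic accuracy of the MIA by category (%% (95%% CI)):")
  add("  %-26s %5s %-14s %-14s %-14s %-14s %-14s", "category", "cases",
      "sens", "spec", "PPV", "NPV", "accuracy")
  pc <- report$per_category
  for (i in seq_len(nrow(pc))) {
    cell <- function(metric) {
      est <- pc[[metric]][i]
      if (is.na(est)) return("N/A")
      paste0(pct(est), ci(pc[[paste0(metric, "_low")]][i],
                          pc[[paste0(metric, "_high")]][i]))
    }
    add("  %-26s %5d %-14s %-14s %-14s %-14s %-14s", pc$category[i],
        pc$cases[i], cell("sensitivity"), cell("specificity"), cell("ppv"),
        cell("npv"), cell("accuracy"))
  }

  co <- report$coincidence
  add("")
  add("ICD-10 code coincidence among category-concordant cases:")
  add("  %-26s %4s %8s %7s %9s %4s %5s", "category", "n", "perf+alm",
      "perfect", "almost", "mod", "low/none")
  for (i in seq_len(nrow(co))) {
    add("  %-26s %4d %8d %7d %9d %4d %2d/%d", co$category[i], co$n[i],
        co$perfect_or_almost[i], co$perfect[i], co$almost_perfect[i],
        co$moderate[i], co$low[i], co$none[i])
  }
  ov <- co[co$category == "overall", ]
  add("  perfect/almost-perfect: %s%%; up to moderate: %s%%",
      pct(ov$perfect_or_almost / ov$n),
      pct((ov$perfect_or_almost + ov$moderate) / ov$n))

  if (print) cat(lines, sep = "\n")
  invisible(lines)
}
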