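#' @import methods
NULL

#' ICD10Code: vector of parsed ICD-10 codes
#'
#' Holds one or more ICD-10 diagnosis codes decomposed into their hierarchy
#' coordinates: the chapter letter, the three-character category (letter plus
#' two digits) and the optional fourth-character subdivision. Construct with
#' [parseIcd10()].
#'
#' @slot raw character, the codes as supplied (trimmed).
#' @slot letter character, the leading chapter letter (A-Z, never U).
#' @slot category3 character, the three-character category, e.g. `"A41"`.
#' @slot subcode character, the fourth character, or `NA` when the code has no
#'   fourth-character subdivision.
#' @name ICD10Code-class
#' @aliases ICD10Code
#' @exportClass ICD10Code
setClass("ICD10Code",
  representation(raw = "character", letter = "character",
                 category3 = "character", subcode = "character"))

setValidity("ICD10Code", function(object) {
  n <- length(object@raw)
  if (length(object@letter) != n || length(object@category3) != n ||
      length(object@subcode) != n)
    return("slot lengths differ")
  if (any(!object@letter %in% setdiff(LETTERS, "U")))
    return("letter must be A-Z excluding U")
  if (any(!grepl("^[A-Z][0-9]{2}$", object@category3)))
    return("category3 must be a letter followed by two digits")
  bad <- !is.na(object@subcode) & !grepl("^[0-9]$", object@subcode)
  if (any(bad)) return("subcode must be a single digit or NA")
  if (any(substr(object@category3, 1, 1) != object@letter))
    return("category3 must start with the chapter letter")
  TRUE
})

#' BlockTable: ICD-10 chapter and block ranges
#'
#' The chapter -> block -> category hierarchy as closed ranges of
#' three-character categories. Block ranges are non-overlapping and each lies
#' inside its chapter's range; chapter ranges are the span of their blocks.
#' Load the packaged WHO (2016 edition) table with [defaultBlockTable()] or a
#' custom table with [readBlockTable()].
#'
#' @slot blocks data.frame with columns `chapter`, `start`, `end`, `label`,
#'   one row per block, ordered by range.
#' @slot chapters data.frame with columns `chapter`, `start`, `end`.
#' @name BlockTable-class
#' @aliases BlockTable
#' @exportClass BlockTable
setClass("BlockTable",
  representation(blocks = "data.frame", chapters = "data.frame"))

setValidity("BlockTable", function(object) {
  b <- object@blocks
  ch <- object@chapters
  need <- c("chapter", "start", "end", "label")
  if (!all(need %in% names(b))) return("blocks needs chapter/start/end/label")
  if (!all(c("chapter", "start", "end") %in% names(ch)))
    return("chapters needs chapter/start/end")
  pat <- "^[A-Z][0-9]{2}$"
  if (any(!grepl(pat, c(b$start, b$end, ch$start, ch$end))))
    return("range endpoints must be three-character categories")
  if (any(b$end < b$start)) return("block end precedes start")
  o <- order(b$start)
  bs <- b[o, ]
  if (nrow(bs) > 1 && any(bs$start[-1] <= bs$end[-nrow(bs)]))
    return("block ranges overlap")
  for (i in seq_len(nrow(b))) {
    j <- match(b$chapter[i], ch$chapter)
    if (is.na(j)) return(sprintf("block %s-%s has unknown chapter %s",
                                 b$start[i], b$end[i], b$chapter[i]))
    if (b$start[i] < ch$start[j] || b$end[i] > ch$end[j])
      return(sprintf("block %s-%s outside chapter %s range",
                     b$start[i], b$end[i], b$chapter[i]))
  }
  TRUE
})

#' CategoryMap: assignment of ICD-10 codes to major disease categories
#'
#' Maps chapter ids, block ids (`"start-end"`) or three-character categories
#' to one of the five disease categories (see [diseaseCategories()]).
#' Resolution order is category > block > chapter, then the fallback.
#' Load the packaged default with [defaultCategoryMap()].
#'
#' @slot chapters named character, chapter id -> category.
#' @slot blocks named character, block id -> category.
#' @slot categories named character, three-character category -> category.
#' @slot default character(1), fallback category.
#' @slot strict logical(1), whether unlocatable codes are errors.
#' @name CategoryMap-class
#' @aliases CategoryMap
#' @exportClass CategoryMap
setClass("CategoryMap",
  representation(chapters = "character", blocks = "character",
                 categories = "character", default = "character",
                 strict = "logical"))

setValidity("CategoryMap", function(object) {
  vals <- c(object@chapters, object@blocks, object@categories, object@default)
  if (any(!vals %in% diseaseCategories()))
    return("all mapped values must be one of the five disease categories")
  if (length(object@default) != 1) return("default must be length 1")
  if (length(object@blocks) && any(!grepl("^[A-Z][0-9]{2}-[A-Z][0-9]{2}$",
                                          names(object@blocks))))
    return("block keys must look like 'A30-A49'")
  if (length(object@categories) && any(!grepl("^[A-Z][0-9]{2}$",
                                              names(object@categories))))
    return("category keys must be three-character categories")
  if (length(object@strict) != 1 || is.na(object@strict))
    return("strict must be TRUE or FALSE")
  TRUE
})

#' EvidenceGrade: strength of pathological and microbiological evidence
#'
#' A vector of per-verdict evidence grades: an ordinal pathology level (0-4),
#' an ordinal microbiology level (0-4), a Y/N flag stating whether the
#' identified microorganisms are in concordance with the histological lesions
#' (not applicable -- `NA` -- when either level is 0), and a logical flag
#' recording histological identification of a microorganism associated with
#' inflammatory changes (which raises the pathology score by one, see
#' [adjustPathology()]).
#'
#' @slot pathology integer in 0..4.
#' @slot microbiology integer in 0..4.
#' @slot microConcordant character `"Y"`, `"N"` or `NA`.
#' @slot histoOrganism logical.
#' @name EvidenceGrade-class
#' @aliases EvidenceGrade
#' @exportClass EvidenceGrade
setClass("EvidenceGrade",
  representation(pathology = "integer", microbiology = "integer",
                 microConcordant = "character", histoOrganism = "logical"))

setValidity("EvidenceGrade", function(object) {
  n <- length(object@pathology)
  if (length(object@microbiology) != n || length(object@microConcordant) != n ||
      length(object@histoOrganism) != n)
    return("slot lengths differ")
  if (any(is.na(object@pathology)) || any(!object@pathology %in% 0:4))
    return("pathology level must be in 0..4")
  if (any(is.na(object@microbiology)) || any(!object@microbiology %in% 0:4))
    return("microbiology level must be in 0..4")
  mc <- object@microConcordant
  if (any(!is.na(mc) & !mc %in% c("Y", "N")))
    return("microConcordant must be 'Y', 'N' or NA")
  notApplicable <- object@pathology == 0L | object@microbiology == 0L
  if (any(notApplicable & !is.na(mc)))
    return("microConcordant must be NA when pathology or microbiology is 0")
  if (any(is.na(object@histoOrganism)))
    return("histoOrganism must be TRUE or FALSE")
  TRUE
})

#' CaseSet: paired MIA/CDA cause-of-death verdicts
#'
#' One row per death, with both arms' verdicts side by side: main cause-of-death
#' ICD-10 code (or the [nonconclusiveCode()] sentinel), optional condition
#' chain, underlying and other-significant condition codes
#' (semicolon-separated), the evidence grade, and the diagnostic certainty
#' derived from it. Build with [readCases()] or [simulateCases()].
#'
#' @slot data data.frame with the documented case columns (see [readCases()]).
#' @name CaseSet-class
#' @aliases CaseSet
#' @exportClass CaseSet
setClass("CaseSet", representation(data = "data.frame"))

setValidity("CaseSet", function(object) {
  d <- object@data
  missing <- setdiff(caseColumns(), names(d))
  if (length(missing))
    return(paste("missing case columns:", paste(missing, collapse = ", ")))
  if (anyDuplicated(d$case_id)) return("case_id values must be unique")
  for (arm in c("mia", "cda")) {
    code <- d[[paste0(arm, "_code")]]
    cert <- d[[paste0(arm, "_certainty")]]
    if (any(!cert %in% certaintyLevels()))
      return(sprintf("%s_certainty has values outside the certainty scale", arm))
    bad <- (code == nonconclusiveCode()) != (cert == "no_diagnosis")
    if (any(bad))
      return(sprintf(
        "case(s) %s: %s verdict must be %s exactly when certainty is no_diagnosis",
        paste(d$case_id[bad], collapse = ", "), arm, nonconclusiveCode()))
  }
  TRUE
})

#' ConfusionMatrix: K x K category cross-tabulation
#'
#' Cross-tabulation of MIA disease categories (rows) against CDA categories
#' (columns, the gold standard); the input to all agreement statistics.
#' Build from cases with [buildConfusionMatrix()] or directly with
#' [ConfusionMatrix()].
#'
#' @slot counts integer matrix, rows = MIA, columns = CDA.
#' @slot categories character, the K category labels.
#' @name ConfusionMatrix-class
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix",
  representation(counts = "matrix", categories = "character"))

setValidity("ConfusionMatrix", function(object) {
  m <- object@counts
  k <- length(object@categories)
  if (k < 2) return("need at least two categories")
  if (!is.numeric(m) || nrow(m) != k || ncol(m) != k)
    return("counts must be a K x K numeric matrix")
  if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
    return("counts must be non-negative integers")
  TRUE
})

#' KappaResult: Cohen's kappa with both standard errors
#'
#' Chance-corrected agreement for a [ConfusionMatrix-class]. Two standard
#' errors are reported: `seNull`, the standard error under the null hypothesis
#' kappa = 0 (used for significance testing), and `seAlt`, the large-sample
#' (Fleiss-Cohen-Everitt) standard error under the alternative, from which the
#' confidence interval is built. See [cohenKappa()].
#'
#' @slot kappa,pObserved,pExpected numeric(1).
#' @slot seNull,seAlt numeric(1).
#' @slot ciLow,ciHigh numeric(1), bounds truncated to \[-1, 1\].
#' @slot level numeric(1), confidence level.
#' @slot n integer(1), number of paired cases.
#' @slot interpretation character(1), Landis-Koch band.
#' @name KappaResult-class
#' @exportClass KappaResult
setClass("KappaResult",
  representation(kappa = "numeric", pObserved = "numeric",
                 pExpected = "numeric", seNull = "numeric", seAlt = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", level = "numeric",
                 n = "integer", interpretation = "character"))

setValidity("KappaResult", function(object) {
  if (object@kappa < -1 - 1e-12 || object@kappa > 1 + 1e-12)
    return("kappa outside [-1, 1]")
  if (object@ciLow > object@kappa + 1e-12 || object@ciHigh < object@kappa - 1e-12)
    return("confidence interval must contain the estimate")
  if (object@seNull < 0 || object@seAlt < 0) return("standard errors must be >= 0")
  TRUE
})

#' SimDesign: design of a synthetic paired-verdict study
#'
#' Parameters of the synthetic-data generator: the number of deaths, the CDA
#' (truth) category distribution, a row-stochastic misclassification matrix
#' P(MIA category | CDA category), the distribution of code-agreement depth
#' among category-concordant pairs, target certainty distributions for the two
#' arms, and the random seed. See [simulateCases()] and [analyticKappa()].
#'
#' @slot nCases integer(1).
#' @slot categoryProbs numeric simplex named by [diseaseCategories()].
#' @slot confusion K x K row-stochastic matrix (rows/cols in category order).
#' @slot depthAgreement numeric named `perfect`, `almost_perfect`, `moderate`,
#'   `low`; the remainder to 1 is the probability of `none`.
#' @slot miaCertainty,cdaCertainty numeric simplices over the coded certainty
#'   levels `low`, `moderate`, `high`, `very_high`.
#' @slot seed integer(1).
#' @name SimDesign-class
#' @exportClass SimDesign
setClass("SimDesign",
  representation(nCases = "integer", categoryProbs = "numeric",
                 confusion = "matrix", depthAgreement = "numeric",
                 miaCertainty = "numeric", cdaCertainty = "numeric",
                 seed = "integer"))

setValidity("SimDesign", function(object) {
  k <- length(diseaseCategories())
  tol <- 1e-9
  if (length(object@nCases) != 1 || is.na(object@nCases) || object@nCases < 1)
    return("nCases must be a positive integer")
  p <- object@categoryProbs
  if (!identical(names(p), diseaseCategories()))
    return("categoryProbs must be named by diseaseCategories()")
  if (any(p < 0) || abs(sum(p) - 1) > tol)
    return("categoryProbs must be a simplex (sum 1, tolerance 1e-9)")
  m <- object@confusion
  if (!all(dim(m) == k)) return("confusion must be K x K")
  if (any(m < 0) || any(abs(rowSums(m) - 1) > tol))
    return("confusion rows must each sum to 1")
  d <- object@depthAgreement
  if (!identical(names(d), c("perfect", "almost_perfect", "moderate", "low")))
    return("depthAgreement must be named perfect/almost_perfect/moderate/low")
  if (any(d < 0) || sum(d) > 1 + tol)
    return("depthAgreement components must be non-negative and sum to <= 1")
  for (nm in c("miaCertainty", "cdaCertainty")) {
    q <- slot(object, nm)
    if (!identical(names(q), c("low", "moderate", "high", "very_high")))
      return(sprintf("%s must be named low/moderate/high/very_high", nm))
    if (any(q < 0) || abs(sum(q) - 1) > tol)
      return(sprintf("%s must be a simplex", nm))
  }
  if (length(object@seed) != 1 || is.na(object@seed))
    return("seed must be a single integer")
  TRUE
})
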