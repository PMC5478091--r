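#' @export
setGeneric("locateCode", function(code, table, ...) standardGeneric("locateCode"))

#' @export
setGeneric("codeCoincidence",
           function(a, b, table, ...) standardGeneric("codeCoincidence"))

#' @export
setGeneric("categorizeCode",
           function(code, map, table, ...) standardGeneric("categorizeCode"))

#' @export
setGeneric("adjustPathology", function(grade) standardGeneric("adjustPathology"))

#' @export
setGeneric("gradeCertainty", function(grade, ...) standardGeneric("gradeCertainty"))

#' @export
setGeneric("buildConfusionMatrix",
           function(cases, map, table, ...) standardGeneric("buildConfusionMatrix"))

#' @export
setGeneric("coincidenceTable",
           function(cases, map, table, ...) standardGeneric("coincidenceTable"))

#' @export
setGeneric("cohenKappa", function(m, ...) standardGeneric("cohenKappa"))

#' @export
setGeneric("overallAgreement", function(m, ...) standardGeneric("overallAgreement"))

#' @export
setGeneric("categoryAccuracy", function(m, ...) standardGeneric("categoryAccuracy"))

#' @export
setGeneric("evaluateCases", function(cases, ...) standardGeneric("evaluateCases"))

#' @export
setGeneric("simulateCases",
           function(design, table, map, ...) standardGeneric("simulateCases"))

#' @export
setGeneric("analyticKappa", function(design) standardGeneric("analyticKappa"))

#' @export
setGeneric("writeCases", function(cases, path, ...) standardGeneric("writeCases"))

#' @export
setGeneric("caseData", function(x) standardGeneric("caseData"))

#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))

#' @export
setGeneric("categoryLabels", function(x) standardGeneric("categoryLabels"))

#' @export
setGeneric("totalCases", function(x) standardGeneric("totalCases"))
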