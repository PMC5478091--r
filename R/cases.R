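#' Columns of a case file
#'
#' The documented header of the case CSV consumed by [readCases()]: one row
#' per death (wide format, both arms side by side, so pairing can never be
#' reconstructed incorrectly). `*_chain`, `*_underlying` and `*_other` hold
#' semicolon-separated ICD-10 codes and may be empty; `*_code` holds the main
#' cause-of-death code or the [nonconclusiveCode()] sentinel; `*_certainty` is
#' optional on input (it is recomputed from the evidence columns and
#' cross-checked when supplied).
#'
#' @return character vector of column names.
#' @export
caseColumns <- function() {
  per_arm <- c("code", "chain", "underlying", "other", "path_level",
               "micro_level", "micro_concordant", "histo_org_inflam",
               "certainty")
  c("case_id", "age_months", "sex",
    paste0("mia_", per_arm), paste0("cda_", per_arm))
}

.mandatoryColumns <- function() {
  setdiff(caseColumns(),
          c("mia_certainty", "cda_certainty",
            paste0(c("mia_", "cda_"), rep(c("chain", "underlying", "other"), each = 2))))
}

#' Read paired cause-of-death cases
#'
#' Reads a comma-delimited UTF-8 case file (header per [caseColumns()]),
#' validates every row, applies the pathology adjustment
#' ([adjustPathology()]), recomputes each arm's diagnostic certainty from the
#' evidence columns, and cross-checks it against any supplied certainty
#' column. Row-level problems (malformed codes, invalid evidence levels,
#' certainty mismatches) are collected and reported together, each naming its
#' `case_id`.
#'
#' @param path path to the case CSV.
#' @param table a [BlockTable-class] (default the packaged WHO table).
#' @param map a [CategoryMap-class] (default the packaged map).
#' @param strict logical; when `TRUE` (default) certainty mismatches and
#'   out-of-range ages (outside 1 month to 15 years) are errors, otherwise
#'   warnings.
#' @return A [CaseSet-class].
#' @examples
#' cs <- readCases(exampleCasesPath())
#' cs
#' @export
readCases <- function(path, table = defaultBlockTable(),
                      map = defaultCategoryMap(), strict = TRUE) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  if (nrow(d) == 0L)
    stop("case file is empty: ", path, call. = FALSE)
  missing <- setdiff(.mandatoryColumns(), names(d))
  if (length(missing))
    stop("case file lacks mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (opt in setdiff(caseColumns(), names(d))) d[[opt]] <- ""
  d <- d[caseColumns()]
  d$age_months <- as.numeric(d$age_months)

  problems <- character(0)
  note <- function(id, msg) problems <<- c(problems, sprintf("%s: %s", id, msg))

  levelsByArm <- list()
  for (arm in c("mia", "cda")) {
    codeCol <- paste0(arm, "_code")
    for (i in seq_len(nrow(d))) {
      code <- trimws(d[[codeCol]][i])
      d[[codeCol]][i] <- code
      if (code != nonconclusiveCode()) {
        parsed <- tryCatch(parseIcd10(code), error = function(e) e)
        if (inherits(parsed, "error")) {
          note(d$case_id[i], sprintf("%s: %s", codeCol,
                                     conditionMessage(parsed)))
          next
        }
        locd <- tryCatch(locateCode(parsed, table), error = function(e) e)
        if (inherits(locd, "error"))
          note(d$case_id[i], sprintf("%s: %s", codeCol,
                                     conditionMessage(locd)))
      }
      for (listCol in paste0(arm, c("_chain", "_underlying", "_other"))) {
        codes <- .splitCodes(d[[listCol]][i])
        if (length(codes)) {
          bad <- tryCatch({parseIcd10(codes); NULL}, error = function(e) e)
          if (!is.null(bad))
            note(d$case_id[i], sprintf("%s: %s", listCol,
                                       conditionMessage(bad)))
        }
        if (endsWith(listCol, "_chain") && length(codes) > 4)
          note(d$case_id[i],
               sprintf("%s: chain longer than four conditions", listCol))
      }
    }
    lv <- suppressWarnings(list(
      p = as.integer(d[[paste0(arm, "_path_level")]]),
      m = as.integer(d[[paste0(arm, "_micro_level")]])))
    conc <- trimws(d[[paste0(arm, "_micro_concordant")]])
    conc[conc == ""] <- NA_character_
    histo <- toupper(trimws(d[[paste0(arm, "_histo_org_inflam")]])) %in%
      c("TRUE", "T", "Y", "YES", "1")
    badLv <- is.na(lv$p) | is.na(lv$m) | !lv$p %in% 0:4 | !lv$m %in% 0:4
    for (i in which(badLv))
      note(d$case_id[i], sprintf("%s evidence levels must be integers 0-4", arm))
    levelsByArm[[arm]] <- list(lv = lv, conc = conc, histo = histo)
  }
  if (length(problems))
    stop("invalid case rows:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)

  # evidence -> certainty, per arm
  for (arm in c("mia", "cda")) {
    lv <- levelsByArm[[arm]]$lv
    conc <- levelsByArm[[arm]]$conc
    histo <- levelsByArm[[arm]]$histo
    grade <- tryCatch(
      adjustPathology(evidenceGrade(lv$p, lv$m, conc, histo)),
      error = function(e) e)
    if (inherits(grade, "error")) stop(grade)
    cert <- as.character(gradeCertainty(grade))
    supplied <- trimws(d[[paste0(arm, "_certainty")]])
    check <- nzchar(supplied)
    mismatch <- check & supplied != cert
    if (any(mismatch)) {
      msg <- sprintf(
        "%s certainty mismatch (supplied vs recomputed) for case(s): %s", arm,
        paste(sprintf("%s (%s vs %s)", d$case_id[mismatch],
                      supplied[mismatch], cert[mismatch]), collapse = ", "))
      if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    }
    d[[paste0(arm, "_certainty")]] <- cert
    d[[paste0(arm, "_path_level")]] <- grade@pathology
    d[[paste0(arm, "_micro_level")]] <- grade@microbiology
    d[[paste0(arm, "_micro_concordant")]] <- grade@microConcordant
    d[[paste0(arm, "_histo_org_inflam")]] <- grade@histoOrganism
  }

  outOfRange <- !is.na(d$age_months) & (d$age_months < 1 | d$age_months > 180)
  if (any(outOfRange)) {
    msg <- paste("age outside the 1 month to 15 years study range for case(s):",
                 paste(d$case_id[outOfRange], collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  d$sex[!d$sex %in% c("M", "F")] <- "unknown"
  rownames(d) <- NULL
  new("CaseSet", data = d)
}

.splitCodes <- function(x) {
  x <- trimws(x)
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' Write a CaseSet back to CSV
#'
#' Writes the case table in the same wide CSV layout [readCases()] consumes;
#' reading the written file back reproduces identical analysis output.
#'
#' @param cases a [CaseSet-class].
#' @param path output path.
#' @param ... unused.
#' @return `path`, invisibly.
#' @export
setMethod("writeCases", signature("CaseSet", "character"),
  function(cases, path, ...) {
    utils::write.csv(cases@data, path, row.names = FALSE, quote = FALSE,
                     na = "")
    invisible(path)
  })

#' @describeIn CaseSet-class the underlying case data.frame.
#' @param x a `CaseSet`.
#' @export
setMethod("caseData", "CaseSet", function(x) x@data)

#' @describeIn CaseSet-class number of paired cases.
#' @export
setMethod("length", "CaseSet", function(x) nrow(x@data))

setMethod("show", "CaseSet", function(object) {
  d <- object@data
  cat(sprintf("CaseSet: %d paired MIA/CDA cause-of-death verdicts\n", nrow(d)))
  cat(sprintf("  MIA nonconclusive: %d; CDA nonconclusive: %d\n",
              sum(d$mia_code == nonconclusiveCode()),
              sum(d$cda_code == nonconclusiveCode())))
})

#' Select the main cause of death
#'
#' The direct cause of death, not the underlying disease, is the main cause:
#' underlying conditions (e.g. HIV infection or malnutrition) never displace
#' the direct condition (bacterial pneumonia in a malnourished toddler, or
#' lymphoma in an HIV-infected child, remain the main cause). This is a
#' deliberate identity on `direct`; it exists so the selection rule is named,
#' tested and documented.
#'
#' @param direct the direct cause-of-death [ICD10Code-class].
#' @param underlying list or [ICD10Code-class] of underlying conditions
#'   (ignored).
#' @return `direct`, unchanged.
#' @examples
#' selectMainCod(parseIcd10("J15.9"), parseIcd10("B20"))
#' @export
selectMainCod <- function(direct, underlying = NULL) {
  stopifnot(is(direct, "ICD10Code"), length(direct) >= 1)
  direct
}
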