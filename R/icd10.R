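#' Parse ICD-10 codes
#'
#' Parses and normalizes one or more ICD-10 diagnosis codes. Input is
#' case-insensitive and separators (a dot or spaces between the category and
#' the fourth character) are ignored, so `"a41 . 5"` parses the same as
#' `"A41.5"`. A code is a chapter letter, two digits, and an optional single
#' fourth-character digit. Chapter XXII (U) codes and dagger/asterisk-suffixed
#' codes are rejected: mortality coding of the kind supported here never uses
#' them.
#'
#' @param text character vector of codes.
#' @return An [ICD10Code-class] vector of the same length.
#' @examples
#' parseIcd10(c("C83.7", "a41 . 5", "N12"))
#' @export
parseIcd10 <- function(text) {
  if (!is.character(text)) text <- as.character(text)
  raw <- trimws(text)
  norm <- toupper(gsub("[. ]", "", raw))
  ok <- nzchar(raw) & grepl("^[A-TV-Z][0-9]{2}[0-9]?$", norm)
  if (any(!ok)) {
    stop("malformed ICD-10 code(s): ",
         paste(sprintf("'%s'", raw[!ok]), collapse = ", "),
         call. = FALSE)
  }
  new("ICD10Code",
      raw = raw,
      letter = substr(norm, 1, 1),
      category3 = substr(norm, 1, 3),
      subcode = ifelse(nchar(norm) == 4, substr(norm, 4, 4), NA_character_))
}

#' @describeIn ICD10Code-class number of codes in the vector.
#' @param x an `ICD10Code` vector.
#' @export
setMethod("length", "ICD10Code", function(x) length(x@raw))

setMethod("show", "ICD10Code", function(object) {
  cat(sprintf("ICD10Code vector of length %d\n", length(object)))
  shown <- utils::head(formatIcd10(object), 8)
  cat(" ", paste(shown, collapse = " "), if (length(object) > 8) "...", "\n")
})

#' Canonical string form of parsed codes
#'
#' Renders an [ICD10Code-class] vector in the canonical `A41.5` / `N12` form
#' (uppercase, dot before the fourth character when present).
#'
#' @param code an `ICD10Code` vector.
#' @return character vector.
#' @export
formatIcd10 <- function(code) {
  stopifnot(is(code, "ICD10Code"))
  ifelse(is.na(code@subcode), code@category3,
         paste0(code@category3, ".", code@subcode))
}

#' Subset an ICD10Code vector
#' @param x an `ICD10Code` vector.
#' @param i index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "ICD10Code", function(x, i, j, ..., drop = TRUE) {
  new("ICD10Code", raw = x@raw[i], letter = x@letter[i],
      category3 = x@category3[i], subcode = x@subcode[i])
})
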