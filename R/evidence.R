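#' Construct evidence grades
#'
#' Vectorized constructor for [EvidenceGrade-class]. The `microConcordant`
#' flag states whether the microorganisms identified are in concordance with
#' the histological lesions observed; it is not applicable (must be `NA`) when
#' either evidence level is 0. `histoOrganism` records histological
#' identification of a microorganism associated with inflammatory changes.
#'
#' @param pathology integer vector, 0-4.
#' @param microbiology integer vector, 0-4.
#' @param microConcordant `"Y"`, `"N"` or `NA`.
#' @param histoOrganism logical.
#' @return An [EvidenceGrade-class] vector.
#' @examples
#' evidenceGrade(3, 3, "Y")
#' @export
evidenceGrade <- function(pathology, microbiology, microConcordant = NA,
                          histoOrganism = FALSE) {
  n <- max(length(pathology), length(microbiology), length(microConcordant),
           length(histoOrganism))
  new("EvidenceGrade",
      pathology = rep_len(as.integer(pathology), n),
      microbiology = rep_len(as.integer(microbiology), n),
      microConcordant = rep_len(as.character(microConcordant), n),
      histoOrganism = rep_len(as.logical(histoOrganism), n))
}

#' @describeIn EvidenceGrade-class number of grades.
#' @param x an `EvidenceGrade` vector.
#' @export
setMethod("length", "EvidenceGrade", function(x) length(x@pathology))

setMethod("show", "EvidenceGrade", function(object) {
  cat(sprintf("EvidenceGrade vector of length %d\n", length(object)))
  i <- seq_len(min(length(object), 8))
  cat(sprintf("  path=%d micro=%d conc=%s histo+=%s",
              object@pathology[i], object@microbiology[i],
              ifelse(is.na(object@microConcordant[i]), "-",
                     object@microConcordant[i]),
              ifelse(object@histoOrganism[i], "T", "F")), sep = "\n")
  if (length(object) > 8) cat("  ...\n")
})

#' Apply the histology-organism pathology adjustment
#'
#' Histological identification of a microorganism associated with inflammatory
#' changes raises the pathology score by one (capped at the scale maximum of
#' 4). The flag is cleared after application, so the adjustment is idempotent
#' and is applied exactly once per verdict, before the certainty lookup.
#'
#' @param grade an [EvidenceGrade-class] vector.
#' @return The adjusted [EvidenceGrade-class] vector.
#' @examples
#' adjustPathology(evidenceGrade(2, 3, "Y", histoOrganism = TRUE))
#' @export
setMethod("adjustPathology", "EvidenceGrade", function(grade) {
  p <- grade@pathology
  up <- grade@histoOrganism
  p[up] <- pmin(p[up] + 1L, 4L)
  initialize(grade, pathology = p,
             histoOrganism = rep(FALSE, length(grade)))
})

# The certainty lookup, encoded cell-for-cell. Dimensions: pathology 0-4,
# microbiology 0-4, flag N/Y. Where the flag is not applicable (either level
# 0) both layers hold the same value.
.certaintyLookup <- local({
  ND <- "no_diagnosis"; L <- "low"; M <- "moderate"; H <- "high"; V <- "very_high"
  # rows p0..p4; per row: m0, m1N,m1Y, m2N,m2Y, m3N,m3Y, m4N,m4Y
  rows <- list(
    c(ND, ND, ND, ND, ND, L, L, M, M),
    c(L,  L,  L,  L,  L,  M, M, M, M),
    c(L,  L,  L,  L,  M,  M, M, M, H),
    c(M,  M,  M,  M,  H,  H, H, H, V),
    c(H,  H,  H,  H,  H,  H, V, V, V))
  arr <- array(NA_character_, dim = c(5, 5, 2),
               dimnames = list(pathology = 0:4, microbiology = 0:4,
                               flag = c("N", "Y")))
  for (p in 1:5) {
    r <- rows[[p]]
    arr[p, 1, c("N", "Y")] <- r[1]
    for (m in 2:5) {
      arr[p, m, "N"] <- r[2 * m - 2]
      arr[p, m, "Y"] <- r[2 * m - 1]
    }
  }
  arr
})

#' Certainty of diagnosis from combined evidence
#'
#' Looks up the level of certainty of a cause-of-death diagnosis from the
#' combination of the pathological and microbiological evidence strengths and
#' the histology-microbiology concordance flag. The lookup matrix is encoded
#' verbatim as data (see [certaintyMatrixTable()]); it is a specification, not
#' a formula. The pathology adjustment ([adjustPathology()]) must be applied
#' first; `gradeCertainty()` applies it itself when the flag is still set.
#'
#' @param grade an [EvidenceGrade-class] vector.
#' @param ... unused.
#' @return ordered factor over [certaintyLevels()].
#' @examples
#' gradeCertainty(evidenceGrade(c(0, 4, 2, 2), c(4, 4, 2, 2),
#'                              c(NA, "Y", "N", "Y")))
#' @export
setMethod("gradeCertainty", "EvidenceGrade", function(grade, ...) {
  if (any(grade@histoOrganism)) grade <- adjustPathology(grade)
  p <- grade@pathology
  m <- grade@microbiology
  f <- grade@microConcordant
  needFlag <- p >= 1L & m >= 1L
  if (any(needFlag & is.na(f))) {
    stop("microConcordant flag required when pathology >= 1 and ",
         "microbiology >= 1 (grade ", paste(which(needFlag & is.na(f)),
         collapse = ", "), ")", call. = FALSE)
  }
  f[is.na(f)] <- "N"  # not-applicable cells are flag-invariant
  out <- .certaintyLookup[cbind(p + 1L, m + 1L, match(f, c("N", "Y")))]
  .asCertainty(out)
})

#' The certainty lookup matrix as a flat table
#'
#' Returns every valid (pathology, microbiology, concordance-flag) cell of the
#' certainty lookup with its certainty level, for audit and export. Cells
#' where the flag is not applicable (either level 0) appear once with flag
#' `NA`.
#'
#' @return data.frame with columns `pathology`, `microbiology`,
#'   `micro_concordant`, `certainty`.
#' @examples
#' head(certaintyMatrixTable())
#' @export
certaintyMatrixTable <- function() {
  cells <- expand.grid(pathology = 0:4, microbiology = 0:4,
                       micro_concordant = c("N", "Y"),
                       stringsAsFactors = FALSE)
  na <- cells$pathology == 0 | cells$microbiology == 0
  cells$micro_concordant[na] <- NA_character_
  cells <- unique(cells)
  cells <- cells[order(cells$pathology, cells$microbiology,
                       cells$micro_concordant, na.last = FALSE), ]
  rownames(cells) <- NULL
  g <- evidenceGrade(cells$pathology, cells$microbiology,
                     cells$micro_concordant)
  cells$certainty <- as.character(gradeCertainty(g))
  cells
}
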