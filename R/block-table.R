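#' Load an ICD-10 chapter/block range table
#'
#' `readBlockTable()` reads a tab-delimited file with columns `chapter`,
#' `start`, `end`, `label` (one row per block; ranges are closed) and validates
#' it: block ranges must not overlap and chapter ranges are derived as the span
#' of each chapter's blocks. `defaultBlockTable()` returns the packaged WHO
#' ICD-10 (2016 edition) chapter and block ranges; pass a different file to
#' analyse under other boundaries.
#'
#' @param path path to a tab-delimited block file.
#' @return A [BlockTable-class] object.
#' @examples
#' bt <- defaultBlockTable()
#' head(blockRanges(bt))
#' @export
readBlockTable <- function(path) {
  b <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character", comment.char = "#")
  need <- c("chapter", "start", "end", "label")
  if (!all(need %in% names(b)))
    stop("block table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  b <- b[order(b$start), , drop = FALSE]
  rownames(b) <- NULL
  ch <- do.call(rbind, lapply(split(b, b$chapter), function(d) {
    data.frame(chapter = d$chapter[1], start = min(d$start), end = max(d$end),
               stringsAsFactors = FALSE)
  }))
  ch <- ch[order(ch$start), , drop = FALSE]
  rownames(ch) <- NULL
  new("BlockTable", blocks = b, chapters = ch)
}

#' @rdname readBlockTable
#' @export
defaultBlockTable <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- readBlockTable(
        system.file("extdata", "icd10_blocks.tsv", package = "CoDagree",
                    mustWork = TRUE))
    }
    cache
  }
})

#' Block and chapter ranges of a BlockTable
#'
#' @param table a [BlockTable-class].
#' @return `blockRanges()`: the block data.frame with a `block` id column
#'   (`"start-end"`); `chapterRanges()`: the chapter data.frame.
#' @export
blockRanges <- function(table) {
  stopifnot(is(table, "BlockTable"))
  b <- table@blocks
  b$block <- paste0(b$start, "-", b$end)
  b
}

#' @rdname blockRanges
#' @export
chapterRanges <- function(table) {
  stopifnot(is(table, "BlockTable"))
  table@chapters
}

setMethod("show", "BlockTable", function(object) {
  cat(sprintf("BlockTable: %d blocks in %d chapters (%s .. %s)\n",
              nrow(object@blocks), nrow(object@chapters),
              min(object@blocks$start), max(object@blocks$end)))
})

#' Locate codes in the ICD-10 hierarchy
#'
#' Returns, for each code, the unique chapter and block whose closed ranges
#' contain its three-character category. Comparison is lexicographic on the
#' (letter, two-digit number) form, which orders categories as the
#' classification does. Codes with equal categories always receive identical
#' coordinates.
#'
#' @param code an [ICD10Code-class] vector.
#' @param table a [BlockTable-class].
#' @param ... unused.
#' @return data.frame with columns `code`, `category3`, `chapter`, `block`.
#' @examples
#' locateCode(parseIcd10(c("A41.5", "J15")), defaultBlockTable())
#' @export
setMethod("locateCode", signature("ICD10Code", "BlockTable"),
  function(code, table, ...) {
    b <- table@blocks
    cat3 <- code@category3
    idx <- vapply(cat3, function(x) {
      i <- which(b$start <= x & x <= b$end)
      if (length(i) == 1L) i else NA_integer_
    }, integer(1))
    if (any(is.na(idx))) {
      stop("ICD-10 category outside all chapter ranges: ",
           paste(unique(cat3[is.na(idx)]), collapse = ", "), call. = FALSE)
    }
    data.frame(code = formatIcd10(code), category3 = cat3,
               chapter = b$chapter[idx],
               block = paste0(b$start[idx], "-", b$end[idx]),
               stringsAsFactors = FALSE)
  })

#' Five-level ICD-10 code coincidence
#'
#' Classifies how deeply two ICD-10 codes agree in the hierarchy:
#' \describe{
#'   \item{perfect}{the full codes are identical (chapter, block and
#'     four-character category; two identical three-character codes with no
#'     fourth character also count as perfect).}
#'   \item{almost_perfect}{the codes coincide up to the first three characters
#'     but are not identical.}
#'   \item{moderate}{same chapter and block, different three-character
#'     category.}
#'   \item{low}{same chapter, different block.}
#'   \item{none}{different chapters.}
#' }
#' The classification is symmetric and `codeCoincidence(a, a)` is always
#' `perfect`.
#'
#' @param a,b [ICD10Code-class] vectors of equal length (or length 1,
#'   recycled).
#' @param table a [BlockTable-class].
#' @param ... unused.
#' @return ordered factor over [coincidenceLevels()].
#' @examples
#' bt <- defaultBlockTable()
#' codeCoincidence(parseIcd10("A40.1"), parseIcd10("A41.5"), bt)
#' @export
setMethod("codeCoincidence", signature("ICD10Code", "ICD10Code", "BlockTable"),
  function(a, b, table, ...) {
    n <- max(length(a), length(b))
    if (length(a) == 1L && n > 1L) a <- a[rep(1L, n)]
    if (length(b) == 1L && n > 1L) b <- b[rep(1L, n)]
    stopifnot(length(a) == length(b))
    la <- locateCode(a, table)
    lb <- locateCode(b, table)
    sameFull <- a@category3 == b@category3 &
      (is.na(a@subcode) & is.na(b@subcode) |
         (!is.na(a@subcode) & !is.na(b@subcode) & a@subcode == b@subcode))
    out <- ifelse(sameFull, "perfect",
           ifelse(a@category3 == b@category3, "almost_perfect",
           ifelse(la$block == lb$block, "moderate",
           ifelse(la$chapter == lb$chapter, "low", "none"))))
    .asCoincidence(out)
  })
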