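#' Load a disease-category map
#'
#' `readCategoryMap()` reads a YAML file with optional `chapters`, `blocks`
#' and `categories` mappings (keys are chapter ids, `"start-end"` block ids,
#' or three-character categories; values are [diseaseCategories()] names) and
#' a `default` fallback. `defaultCategoryMap()` returns the packaged default:
#' chapter I and the pneumonia / acute lower-respiratory / CNS-infection /
#' peritonitis / pyelonephritis blocks map to infectious diseases, the
#' malignant chapter II blocks (C00-C97) to malignant tumors, chapter XVII to
#' congenital malformations, R95-R99 to nonconclusive, everything else to
#' other diseases. The map is data, not code: causes of death are categorized
#' by the clinical nature of the condition, which does not follow ICD-10
#' chapters exactly, so site-specific edits are expected.
#'
#' @param path path to a YAML category-map file.
#' @param strict logical; if `TRUE` (default) codes that cannot be located in
#'   the block table are errors, otherwise they fall back to the default
#'   category with a warning.
#' @return A [CategoryMap-class] object.
#' @examples
#' defaultCategoryMap()
#' @export
readCategoryMap <- function(path, strict = TRUE) {
  y <- yaml::read_yaml(path)
  grab <- function(el) {
    if (is.null(y[[el]]) || length(y[[el]]) == 0) {
      stats::setNames(character(0), character(0))
    } else {
      unlist(y[[el]])
    }
  }
  if (is.null(y$default))
    stop("category map must declare a 'default' category", call. = FALSE)
  new("CategoryMap", chapters = grab("chapters"), blocks = grab("blocks"),
      categories = grab("categories"), default = y$default, strict = strict)
}

#' @rdname readCategoryMap
#' @export
defaultCategoryMap <- function(strict = TRUE) {
  readCategoryMap(
    system.file("extdata", "default_category_map.yaml", package = "CoDagree",
                mustWork = TRUE),
    strict = strict)
}

setMethod("show", "CategoryMap", function(object) {
  cat(sprintf(
    "CategoryMap: %d chapter, %d block, %d category entries; default '%s'%s\n",
    length(object@chapters), length(object@blocks), length(object@categories),
    object@default, if (object@strict) " (strict)" else ""))
})

#' Assign codes to major disease categories
#'
#' Resolves each code against a [CategoryMap-class]: an explicit
#' three-character category entry wins over a block entry, which wins over a
#' chapter entry; unmatched codes get the map's default. Character input is
#' accepted and parsed; the [nonconclusiveCode()] sentinel maps to
#' `"nonconclusive"`.
#'
#' @param code an [ICD10Code-class] vector, or a character vector of codes
#'   possibly containing the sentinel.
#' @param map a [CategoryMap-class].
#' @param table a [BlockTable-class] used to resolve blocks and chapters.
#' @param ... unused.
#' @return factor over [diseaseCategories()].
#' @examples
#' categorizeCode(parseIcd10(c("C83.7", "J15", "Q24")),
#'                defaultCategoryMap(), defaultBlockTable())
#' @export
setMethod("categorizeCode", signature("ICD10Code", "CategoryMap", "BlockTable"),
  function(code, map, table, ...) {
    loc <- tryCatch(locateCode(code, table), error = function(e) e)
    if (inherits(loc, "error")) {
      if (map@strict) stop(loc)
      warning("unlocatable code(s) assigned the default category: ",
              conditionMessage(loc), call. = FALSE)
      # per-code fallback: locate one at a time
      out <- vapply(seq_along(code), function(i) {
        l <- tryCatch(locateCode(code[i], table), error = function(e) NULL)
        if (is.null(l)) return(map@default)
        .resolveCategory(code@category3[i], l$chapter, l$block, map)
      }, character(1))
      return(.asCategory(out))
    }
    out <- vapply(seq_along(code), function(i) {
      .resolveCategory(code@category3[i], loc$chapter[i], loc$block[i], map)
    }, character(1))
    .asCategory(out)
  })

#' @rdname categorizeCode
#' @export
setMethod("categorizeCode", signature("character", "CategoryMap", "BlockTable"),
  function(code, map, table, ...) {
    out <- rep(NA_character_, length(code))
    isNc <- code == nonconclusiveCode()
    out[isNc] <- "nonconclusive"
    if (any(!isNc))
      out[!isNc] <- as.character(
        categorizeCode(parseIcd10(code[!isNc]), map, table))
    .asCategory(out)
  })

.resolveCategory <- function(cat3, chapter, block, map) {
  if (cat3 %in% names(map@categories)) return(unname(map@categories[cat3]))
  if (block %in% names(map@blocks)) return(unname(map@blocks[block]))
  if (chapter %in% names(map@chapters)) return(unname(map@chapters[chapter]))
  map@default
}
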