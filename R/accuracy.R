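#' Per-category diagnostic accuracy of the MIA
#'
#' One-vs-rest collapse of the confusion matrix for each category: with the
#' CDA (columns) as gold standard, `tp` is the diagonal cell, `fn` the rest of
#' the column, `fp` the rest of the row, and `tn` the remainder, so
#' tp + fp + fn + tn = n for every category. Sensitivity, specificity,
#' positive and negative predictive values and accuracy (proportion correctly
#' classified) are reported with exact [clopperPearson()] intervals. A metric
#' whose denominator is zero (e.g. PPV of a category the MIA never assigned)
#' is not applicable and returned as `NA`, never 0/0.
#'
#' @param m a [ConfusionMatrix-class].
#' @param category a single category label, or `NULL` (default) for all.
#' @param level confidence level.
#' @param ... unused.
#' @return data.frame with one row per category: `category`, `cases` (CDA
#'   column total), `tp`, `fp`, `fn`, `tn`, and for each of `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy` the point estimate and
#'   `*_low`/`*_high` interval bounds (proportions in \[0, 1\]).
#' @examples
#' categoryAccuracy(exampleConfusionMatrix())
#' @export
setMethod("categoryAccuracy", "ConfusionMatrix",
  function(m, category = NULL, level = 0.95, ...) {
    cats <- if (is.null(category)) m@categories else category
    if (!all(cats %in% m@categories))
      stop("unknown category: ", paste(setdiff(cats, m@categories),
                                       collapse = ", "), call. = FALSE)
    counts <- m@counts
    n <- sum(counts)
    one <- function(cc) {
      i <- match(cc, m@categories)
      tp <- counts[i, i]
      fn <- sum(counts[, i]) - tp
      fp <- sum(counts[i, ]) - tp
      tn <- n - tp - fn - fp
      metric <- function(num, den) {
        if (den == 0) {
          data.frame(est = NA_real_, low = NA_real_, high = NA_real_)
        } else {
          ci <- clopperPearson(num, den, level)
          data.frame(est = num / den, low = ci$low, high = ci$high)
        }
      }
      sens <- metric(tp, tp + fn)
      spec <- metric(tn, tn + fp)
      ppv <- metric(tp, tp + fp)
      npv <- metric(tn, tn + fn)
      acc <- metric(tp + tn, n)
      data.frame(category = cc, cases = tp + fn, tp = tp, fp = fp, fn = fn,
                 tn = tn,
                 sensitivity = sens$est, sensitivity_low = sens$low,
                 sensitivity_high = sens$high,
                 specificity = spec$est, specificity_low = spec$low,
                 specificity_high = spec$high,
                 ppv = ppv$est, ppv_low = ppv$low, ppv_high = ppv$high,
                 npv = npv$est, npv_low = npv$low, npv_high = npv$high,
                 accuracy = acc$est, accuracy_low = acc$low,
                 accuracy_high = acc$high,
                 stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, lapply(cats, one))
    rownames(out) <- NULL
    out
  })
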