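#' Cohen's kappa with null and large-sample standard errors
#'
#' Chance-corrected agreement between the two arms of a
#' [ConfusionMatrix-class]. With cell proportions \eqn{p_{ij}}, row (MIA)
#' marginals \eqn{r_i} and column (CDA) marginals \eqn{c_i}:
#' \deqn{p_o = \sum_i p_{ii}, \quad p_e = \sum_i r_i c_i, \quad
#'       \kappa = (p_o - p_e)/(1 - p_e).}
#' Two standard errors are computed and both reported, because they answer
#' different questions. The null SE (for testing kappa = 0) is
#' \deqn{SE_0 = \sqrt{p_e + p_e^2 - \sum_i r_i c_i (r_i + c_i)} /
#'       ((1 - p_e)\sqrt{n}),}
#' and the confidence interval uses the large-sample (Fleiss-Cohen-Everitt)
#' variance under the alternative,
#' \deqn{\widehat{var}(\kappa) = \frac{A + B - C}{n (1 - p_e)^4}} with
#' \eqn{A = \sum_i p_{ii} [(1-p_e) - (r_i + c_i)(1 - p_o)]^2},
#' \eqn{B = (1-p_o)^2 \sum_{i \ne j} p_{ij} (c_i + r_j)^2} and
#' \eqn{C = (p_o p_e - 2 p_e + p_o)^2}. The interval
#' \eqn{\kappa \pm z_{1-\alpha/2} SE_{alt}} is truncated to \eqn{[-1, 1]}.
#'
#' @param m a [ConfusionMatrix-class] with at least 2 cases.
#' @param level confidence level (default 0.95).
#' @param ... unused.
#' @return A [KappaResult-class].
#' @examples
#' cohenKappa(exampleConfusionMatrix())
#' @export
setMethod("cohenKappa", "ConfusionMatrix", function(m, level = 0.95, ...) {
  counts <- m@counts
  n <- sum(counts)
  if (n < 2) stop("need at least two paired cases", call. = FALSE)
  p <- counts / n
  r <- rowSums(p)
  cl <- colSums(p)
  po <- sum(diag(p))
  pe <- sum(r * cl)
  if (pe >= 1 - .Machine$double.eps^0.5)
    stop("degenerate marginals: expected agreement is 1, kappa undefined",
         call. = FALSE)
  kappa <- (po - pe) / (1 - pe)
  # clamp tiny negative values from floating-point cancellation
  seNull <- sqrt(max(0, pe + pe^2 - sum(r * cl * (r + cl)))) /
    ((1 - pe) * sqrt(n))
  A <- sum(diag(p) * ((1 - pe) - (r + cl) * (1 - po))^2)
  cross <- outer(cl, r, `+`)^2  # [i, j] = (c_i + r_j)^2
  off <- p * cross              # p_ij * (c_i + r_j)^2
  diag(off) <- 0
  B <- (1 - po)^2 * sum(off)
  C <- (po * pe - 2 * pe + po)^2
  seAlt <- sqrt(max(0, A + B - C) / (n * (1 - pe)^4))
  z <- stats::qnorm(1 - (1 - level) / 2)
  new("KappaResult", kappa = kappa, pObserved = po, pExpected = pe,
      seNull = seNull, seAlt = seAlt,
      ciLow = max(-1, kappa - z * seAlt), ciHigh = min(1, kappa + z * seAlt),
      level = level, n = as.integer(n),
      interpretation = interpretKappa(kappa))
})

setMethod("show", "KappaResult", function(object) {
  cat(sprintf(
    "Cohen's kappa: %.2f (SE under H0 %.4f; %d%% CI %.2f-%.2f, large-sample SE %.4f)\n",
    object@kappa, object@seNull, round(100 * object@level), object@ciLow,
    object@ciHigh, object@seAlt))
  cat(sprintf("  observed agreement %.3f, expected %.3f, n = %d; %s concordance\n",
              object@pObserved, object@pExpected, object@n,
              object@interpretation))
})

#' Landis-Koch interpretation of kappa
#'
#' Maps kappa values to the conventional agreement bands: below 0 `poor`,
#' 0-0.20 `slight`, 0.21-0.40 `fair`, 0.41-0.60 `moderate`, 0.61-0.80
#' `substantial`, 0.81-1.00 `almost perfect` (band boundaries closed on the
#' upper end).
#'
#' @param kappa numeric vector in \[-1, 1\].
#' @return character vector of band labels.
#' @examples
#' interpretKappa(c(0.70, 1, -0.2))
#' @export
interpretKappa <- function(kappa) {
  stopifnot(all(kappa >= -1 - 1e-12 & kappa <= 1 + 1e-12))
  labels <- c("poor", "slight", "fair", "moderate", "substantial",
              "almost perfect")
  labels[1L + (kappa >= 0) + (kappa > 0.20) + (kappa > 0.40) +
           (kappa > 0.60) + (kappa > 0.80)]
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Computes the exact interval from beta quantiles:
#' lower = \eqn{B_{\alpha/2}(k, n-k+1)}, upper =
#' \eqn{B_{1-\alpha/2}(k+1, n-k)}, with lower = 0 when k = 0 and upper = 1
#' when k = n (the boundary cases reduce to one-sided intervals at level
#' \eqn{1-\alpha/2}).
#'
#' @param k number of successes (vectorized).
#' @param n number of trials.
#' @param level confidence level (default 0.95).
#' @return data.frame with columns `low`, `high`.
#' @examples
#' clopperPearson(c(7, 0, 39), c(7, 2, 42))
#' @export
clopperPearson <- function(k, n, level = 0.95) {
  if (any(is.na(k)) || any(is.na(n)) || any(n < 1) || any(k < 0) || any(k > n))
    stop("need 0 <= k <= n with n >= 1", call. = FALSE)
  alpha <- 1 - level
  low <- ifelse(k == 0, 0, stats::qbeta(alpha / 2, k, n - k + 1))
  high <- ifelse(k == n, 1, stats::qbeta(1 - alpha / 2, k + 1, n - k))
  data.frame(low = low, high = high)
}

#' Overall agreement with exact confidence interval
#'
#' The proportion of cases on the confusion-matrix diagonal, with its
#' Clopper-Pearson interval.
#'
#' @param m a [ConfusionMatrix-class].
#' @param level confidence level.
#' @param ... unused.
#' @return list with `agree`, `n`, `proportion`, `ci_low`, `ci_high`.
#' @examples
#' overallAgreement(exampleConfusionMatrix())
#' @export
setMethod("overallAgreement", "ConfusionMatrix", function(m, level = 0.95, ...) {
  agree <- sum(diag(m@counts))
  n <- sum(m@counts)
  ci <- clopperPearson(agree, n, level)
  list(agree = agree, n = n, proportion = agree / n,
       ci_low = ci$low, ci_high = ci$high)
})
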