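test_that("kappa on the packaged matrix matches its frozen reference values", {
  kp <- cohenKappa(exampleConfusionMatrix())
  # reference values computed independently (direct summation and the
  # published large-sample variance formula) and frozen
  expect_equal(kp@kappa, 0.7038391224862887, tolerance = 1e-12)
  expect_equal(kp@pObserved, 48 / 54, tolerance = 1e-12)
  expect_equal(kp@pExpected, 1822 / 2916, tolerance = 1e-12)
  expect_equal(kp@seNull, 0.09564069561383537, tolerance = 1e-10)
  expect_equal(kp@seAlt, 0.1101559085034023, tolerance = 1e-10)
  z <- stats::qnorm(0.975)
  expect_equal(kp@ciLow, 0.7038391224862887 - z * 0.1101559085034023,
               tolerance = 1e-9)
  expect_equal(kp@ciHigh, 0.7038391224862887 + z * 0.1101559085034023,
               tolerance = 1e-9)
  expect_equal(kp@interpretation, "substantial")
})

test_that("kappa equals a direct-summation oracle on random matrices", {
  set.seed(101)
  for (i in 1:1000) {
    k <- sample(2:6, 1)
    cm <- randomConfusion(k = k, lambda = sample(1:6, 1))
    expect_equal(cohenKappa(cm)@kappa, bruteForceKappa(confusionCounts(cm)),
                 tolerance = 1e-12)
  }
})

test_that("kappa hits its analytic anchors and bounds", {
  diagm <- ConfusionMatrix(diag(c(5, 3, 2)), categories = c("a", "b", "c"))
  expect_equal(cohenKappa(diagm)@kappa, 1)
  # observed == expected under independence
  indep <- ConfusionMatrix(outer(c(2, 4), c(3, 3)) / 6,
                           categories = c("a", "b"))
  expect_equal(cohenKappa(indep)@kappa, 0, tolerance = 1e-12)
  # kappa never exceeds raw agreement
  set.seed(7)
  for (i in 1:50) {
    cm <- randomConfusion()
    kp <- cohenKappa(cm)
    expect_lte(kp@kappa, kp@pObserved + 1e-12)
    expect_gte(kp@ciLow, -1)
    expect_lte(kp@ciHigh, 1)
    expect_true(kp@ciLow <= kp@kappa && kp@kappa <= kp@ciHigh)
  }
  degenerate <- ConfusionMatrix(matrix(c(4, 0, 0, 0), 2),
                                categories = c("a", "b"))
  expect_error(cohenKappa(degenerate), "undefined")
})

test_that("Landis-Koch bands are closed on the upper end", {
  expect_equal(interpretKappa(c(-0.2, 0, 0.20, 0.21, 0.40, 0.41, 0.60, 0.61,
                                0.70, 0.80, 0.81, 1.0)),
               c("poor", "slight", "slight", "fair", "fair", "moderate",
                 "moderate", "substantial", "substantial", "substantial",
                 "almost perfect", "almost perfect"))
})

test_that("exact binomial intervals match binom.test and the boundary rules", {
  ref <- clopperPearson(c(7, 0, 39), c(7, 2, 42))
  expect_equal(round(ref$low, 2), c(0.59, 0.00, 0.81))
  expect_equal(round(ref$high, 2), c(1.00, 0.84, 0.99))
  expect_identical(clopperPearson(0, 10)$low, 0)
  expect_identical(clopperPearson(10, 10)$high, 1)
  expect_error(clopperPearson(5, 4), "0 <= k <= n")

  set.seed(5)
  for (i in 1:40) {
    n <- sample(1:60, 1)
    k <- sample(0:n, 1)
    got <- clopperPearson(k, n)
    want <- stats::binom.test(k, n)$conf.int
    expect_equal(c(got$low, got$high), as.numeric(want), tolerance = 1e-12)
  }
})

test_that("exact intervals achieve nominal coverage in simulation", {
  set.seed(77)
  for (p in c(0.1, 0.5, 0.9)) {
    k <- stats::rbinom(10000, 20, p)
    ci <- clopperPearson(k, 20)
    coverage <- mean(ci$low <= p & p <= ci$high)
    mcErr <- sqrt(0.95 * 0.05 / 10000)
    expect_gte(coverage, 0.95 - 3 * mcErr)
  }
})

test_that("one-vs-rest accuracy cells always account for every case", {
  set.seed(13)
  for (i in 1:25) {
    cm <- randomConfusion()
    acc <- categoryAccuracy(cm)
    expect_true(all(acc$tp + acc$fp + acc$fn + acc$tn == totalCases(cm)))
    defined <- !is.na(acc$sensitivity)
    expect_true(all(acc$sensitivity_low[defined] <=
                      acc$sensitivity[defined] + 1e-12))
    expect_true(all(acc$sensitivity_high[defined] >=
                      acc$sensitivity[defined] - 1e-12))
  }
  diagm <- ConfusionMatrix(diag(c(4, 5, 6)), categories = c("a", "b", "c"))
  accd <- categoryAccuracy(diagm)
  expect_true(all(accd[, c("sensitivity", "specificity", "ppv", "npv",
                           "accuracy")] == 1))
})

test_that("overall agreement covers the degenerate extremes", {
  expect_equal(overallAgreement(
    ConfusionMatrix(diag(c(3, 3)), categories = c("a", "b")))$proportion, 1)
  offdiag <- ConfusionMatrix(matrix(c(0, 2, 3, 0), 2),
                             categories = c("a", "b"))
  expect_equal(overallAgreement(offdiag)$proportion, 0)
})
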