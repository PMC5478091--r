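test_that("generation is deterministic under a fixed seed", {
  d1 <- caseData(simulateCases(simDesign(nCases = 40, seed = 99)))
  d2 <- caseData(simulateCases(simDesign(nCases = 40, seed = 99)))
  expect_identical(d1, d2)
  d3 <- caseData(simulateCases(simDesign(nCases = 40, seed = 100)))
  expect_false(identical(d1, d3))
})

test_that("a degenerate identity design yields perfect agreement throughout", {
  design <- simDesign(
    nCases = 60,
    categoryProbs = c(infectious_diseases = 0.6, malignant_tumors = 0.2,
                      congenital_malformations = 0.1, other_diseases = 0.1,
                      nonconclusive = 0),
    confusion = diag(5),
    depthAgreement = c(perfect = 1, almost_perfect = 0, moderate = 0, low = 0),
    seed = 3)
  cs <- simulateCases(design)
  cm <- buildConfusionMatrix(cs)
  expect_equal(cohenKappa(cm)@kappa, 1)
  co <- coincidenceTable(cs)
  ov <- co[co$category == "overall", ]
  expect_equal(ov$perfect, ov$n)
  expect_equal(analyticKappa(design), 1)
})

test_that("analytic kappa is zero when the arms are independent", {
  marg <- c(0.5, 0.2, 0.1, 0.15, 0.05)
  design <- simDesign(
    categoryProbs = stats::setNames(c(0.6, 0.2, 0.1, 0.1, 0),
                                    diseaseCategories()),
    confusion = matrix(rep(marg, 5), 5, byrow = TRUE),
    seed = 1)
  expect_equal(analyticKappa(design), 0, tolerance = 1e-12)
})

test_that("uniform misclassification drives estimated kappa towards zero", {
  design <- simDesign(
    nCases = 4000,
    categoryProbs = stats::setNames(rep(0.2, 5), diseaseCategories()),
    confusion = matrix(0.2, 5, 5),
    seed = 12)
  kp <- cohenKappa(buildConfusionMatrix(simulateCases(design)))
  expect_lt(abs(kp@kappa), 3 * kp@seAlt)
})

test_that("estimated kappa converges to the analytic value at large n", {
  design <- simDesign(nCases = 20000, seed = 31)
  kp <- cohenKappa(buildConfusionMatrix(simulateCases(design)))
  expect_equal(kp@kappa, analyticKappa(design), tolerance = 3 * kp@seAlt)
})

test_that("study-scale replicates recover the analytic kappa on average", {
  design <- simDesign(seed = 0)
  target <- analyticKappa(design)
  R <- 500
  ks <- vapply(seq_len(R), function(r) {
    d <- simDesign(seed = 1000 + r)
    cohenKappa(buildConfusionMatrix(simulateCases(d)))@kappa
  }, numeric(1))
  mcSe <- stats::sd(ks) / sqrt(R)
  expect_lt(abs(mean(ks) - target), 3 * mcSe)
})

test_that("coincidence depths among concordant pairs match the design", {
  probs <- c(perfect = 0.45, almost_perfect = 0.25, moderate = 0.15,
             low = 0.10)  # remainder 0.05 -> none
  design <- simDesign(
    nCases = 10000,
    categoryProbs = stats::setNames(c(1, 0, 0, 0, 0), diseaseCategories()),
    confusion = diag(5),
    depthAgreement = probs,
    seed = 21)
  co <- coincidenceTable(simulateCases(design))
  ov <- co[co$category == "overall", ]
  observed <- c(ov$perfect, ov$almost_perfect, ov$moderate, ov$low, ov$none)
  expected <- c(probs, none = 1 - sum(probs))
  gof <- stats::chisq.test(observed, p = expected)
  expect_gt(gof$p.value, 0.01)
})

test_that("simulated series feed the whole pipeline and round-trip via CSV", {
  design <- readSimDesign(system.file("extdata", "example_design.yaml",
                                      package = "CoDagree"))
  expect_equal(design@nCases, 54L)
  cs <- simulateCases(design)
  tmp <- tempfile(fileext = ".csv")
  writeCases(cs, tmp)
  cs2 <- readCases(tmp)
  expect_equal(caseData(cs2), caseData(cs))
  rep <- evaluateCases(cs2)
  expect_true(is.finite(rep$kappa$estimate))
})

test_that("invalid designs are rejected by the validity checks", {
  expect_error(simDesign(categoryProbs = stats::setNames(
    c(0.5, 0.2, 0.1, 0.1, 0.2), diseaseCategories())), "simplex")
  bad <- matrix(0.2, 5, 5); bad[1, 1] <- 0.5
  expect_error(simDesign(confusion = bad), "rows")
  expect_error(simDesign(depthAgreement = c(perfect = 0.9,
    almost_perfect = 0.2, moderate = 0, low = 0)), "depthAgreement")
})
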