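test_that("the evaluation report carries every analysis block coherently", {
  rep <- evaluateCases(readCases(exampleCasesPath()))
  expect_named(rep, c("n_cases", "confusion", "kappa", "overall_agreement",
                      "per_category", "coincidence"))
  expect_equal(rep$confusion$n, rep$n_cases)
  expect_equal(sum(rep$confusion$row_totals), rep$n_cases)
  expect_equal(rep$overall_agreement$agree,
               rep$coincidence$n[rep$coincidence$category == "overall"])
  expect_equal(rep$kappa$interpretation, "substantial")

  tmp <- tempfile(fileext = ".json")
  writeReportJson(rep, tmp)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(back$kappa$estimate, rep$kappa$estimate, tolerance = 1e-12)
  expect_equal(back$overall_agreement$n, 54)
  # not-applicable metrics are null in JSON, not 0/0
  ppv <- back$per_category$ppv[back$per_category$category ==
                                 "congenital_malformations"]
  expect_true(is.na(ppv) || is.null(ppv))

  lines <- renderReport(rep, print = FALSE)
  expect_true(any(grepl("Kappa: 0.70 \\(standard error 0.0956", lines)))
  expect_true(any(grepl("48/54 = 89%", lines)))
  expect_true(any(grepl("N/A", lines)))
})

test_that("the certainty filter restricts the analysed cases", {
  cs <- readCases(exampleCasesPath())
  rep <- evaluateCases(cs, minCertainty = "high")
  d <- caseData(cs)
  keep <- sum(d$mia_certainty %in% c("high", "very_high") &
                d$cda_certainty %in% c("high", "very_high"))
  expect_equal(rep$n_cases, keep)
  expect_lt(rep$n_cases, 54)
})

test_that("the command-line front end evaluates, simulates and fails loudly", {
  skip_on_os("windows")
  cli <- system.file("cli", "codagree.R", package = "CoDagree")
  rscript <- file.path(R.home("bin"), "Rscript")
  lib <- .libPaths()[1]
  outJson <- tempfile(fileext = ".json")

  res <- system2(rscript, c(cli, "evaluate", "--input", exampleCasesPath(),
                            "--out", outJson),
                 stdout = TRUE, stderr = TRUE,
                 env = paste0("R_LIBS_USER=", lib))
  expect_null(attr(res, "status"))
  rep <- jsonlite::read_json(outJson, simplifyVector = TRUE)
  expect_equal(round(rep$kappa$estimate, 2), 0.7)

  # simulate -> evaluate round trip under an identity design
  designYml <- tempfile(fileext = ".yaml")
  writeLines(c("n_cases: 30", "seed: 5",
               "depth_agreement: {perfect: 1.0, almost_perfect: 0.0, moderate: 0.0, low: 0.0}",
               "confusion:",
               "  - [1.0, 0.0, 0.0, 0.0, 0.0]",
               "  - [0.0, 1.0, 0.0, 0.0, 0.0]",
               "  - [0.0, 0.0, 1.0, 0.0, 0.0]",
               "  - [0.0, 0.0, 0.0, 1.0, 0.0]",
               "  - [0.0, 0.0, 0.0, 0.0, 1.0]"), designYml)
  simCsv <- tempfile(fileext = ".csv")
  res2 <- system2(rscript, c(cli, "simulate", "--design", designYml,
                             "--out", simCsv),
                  stdout = TRUE, stderr = TRUE,
                  env = paste0("R_LIBS_USER=", lib))
  expect_null(attr(res2, "status"))
  rep2 <- evaluateCases(readCases(simCsv))
  expect_equal(rep2$overall_agreement$proportion, 1)
  expect_equal(rep2$kappa$estimate, 1)

  # identical seeds give identical files
  simCsv2 <- tempfile(fileext = ".csv")
  system2(rscript, c(cli, "simulate", "--design", designYml, "--out", simCsv2),
          stdout = TRUE, stderr = TRUE, env = paste0("R_LIBS_USER=", lib))
  expect_identical(readLines(simCsv2), readLines(simCsv))

  # empty input exits nonzero
  emptyCsv <- tempfile(fileext = ".csv")
  writeLines(paste(caseColumns(), collapse = ","), emptyCsv)
  res3 <- suppressWarnings(
    system2(rscript, c(cli, "evaluate", "--input", emptyCsv,
                       "--out", tempfile()),
            stdout = TRUE, stderr = TRUE,
            env = paste0("R_LIBS_USER=", lib)))
  expect_false(is.null(attr(res3, "status")))
})
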