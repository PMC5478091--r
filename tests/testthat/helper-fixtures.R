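# Shared helpers: random valid codes, small confusion matrices, temp tables.

# every category3 in a closed block range (may span letters)
expandRange <- function(start, end) {
  ls <- LETTERS[match(substr(start, 1, 1), LETTERS):
                match(substr(end, 1, 1), LETTERS)]
  unlist(lapply(seq_along(ls), function(i) {
    lo <- if (i == 1) as.integer(substr(start, 2, 3)) else 0L
    hi <- if (i == length(ls)) as.integer(substr(end, 2, 3)) else 99L
    sprintf("%s%02d", ls[i], lo:hi)
  }))
}

# sample n random parseable codes from the packaged block table
randomCodes <- function(n, withSubcode = TRUE) {
  b <- blockRanges(defaultBlockTable())
  cat3 <- vapply(sample.int(nrow(b), n, replace = TRUE), function(i) {
    sample(expandRange(b$start[i], b$end[i]), 1)
  }, character(1))
  if (withSubcode) paste0(cat3, ".", sample(0:9, n, replace = TRUE)) else cat3
}

# random K x K count matrix with a positive total
randomConfusion <- function(k = 5, lambda = 4) {
  repeat {
    m <- matrix(stats::rpois(k * k, lambda), k, k)
    if (sum(m) >= 2 && sum(diag(m)) < sum(m)) break
  }
  ConfusionMatrix(m, categories = paste0("cat", seq_len(k)))
}

# direct-summation kappa oracle, independent of the package implementation
bruteForceKappa <- function(counts) {
  n <- sum(counts)
  po <- 0; pe <- 0
  k <- nrow(counts)
  for (i in seq_len(k)) {
    po <- po + counts[i, i] / n
    pe <- pe + (sum(counts[i, ]) / n) * (sum(counts[, i]) / n)
  }
  (po - pe) / (1 - pe)
}

# minimal one-row case table writer for readCases error-path tests
writeCaseCsv <- function(rows, path = tempfile(fileext = ".csv")) {
  template <- utils::read.csv(exampleCasesPath(), colClasses = "character")
  d <- template[rows, , drop = FALSE]
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  path
}
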