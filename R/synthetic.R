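#' Design a synthetic paired-verdict study
#'
#' Constructs a [SimDesign-class]. The defaults are the conditions of a
#' 54-death pediatric MIA-vs-CDA validation series: the CDA truth
#' distribution (42 infectious, 7 malignant, 2 congenital, 3 other, 0
#' nonconclusive), the MIA misclassification rows conditional on the CDA
#' category, a code-depth agreement distribution of 24/8/4/3 (perfect /
#' almost-perfect / moderate / low) over the 48 concordant pairs with the
#' remaining mass on `none`, and certainty distributions of 3/7/20/24
#' (low/moderate/high/very-high) for the CDA and 4/11/17/20 over the 52 coded
#' MIA verdicts.
#'
#' @param nCases number of deaths.
#' @param categoryProbs CDA category simplex named by [diseaseCategories()].
#' @param confusion K x K row-stochastic matrix, P(MIA category | CDA
#'   category), rows and columns in category order.
#' @param depthAgreement named probabilities (`perfect`, `almost_perfect`,
#'   `moderate`, `low`) of code-agreement depth among category-concordant
#'   pairs; the remainder to 1 is `none`.
#' @param miaCertainty,cdaCertainty simplices over `low`, `moderate`, `high`,
#'   `very_high` for coded verdicts.
#' @param seed integer random seed.
#' @return A [SimDesign-class].
#' @examples
#' analyticKappa(simDesign())
#' @export
simDesign <- function(nCases = 54,
                      categoryProbs = c(infectious_diseases = 42,
                                        malignant_tumors = 7,
                                        congenital_malformations = 2,
                                        other_diseases = 3,
                                        nonconclusive = 0) / 54,
                      confusion = rbind(
                        c(39, 0, 0, 1, 2) / 42,
                        c(0, 7, 0, 0, 0) / 7,
                        c(2, 0, 0, 0, 0) / 2,
                        c(1, 0, 0, 2, 0) / 3,
                        c(0, 0, 0, 0, 1)),
                      depthAgreement = c(perfect = 24, almost_perfect = 8,
                                         moderate = 4, low = 3) / 48,
                      miaCertainty = c(low = 4, moderate = 11, high = 17,
                                       very_high = 20) / 52,
                      cdaCertainty = c(low = 3, moderate = 7, high = 20,
                                       very_high = 24) / 54,
                      seed = 1) {
  dimnames(confusion) <- list(diseaseCategories(), diseaseCategories())
  new("SimDesign", nCases = as.integer(nCases),
      categoryProbs = categoryProbs[diseaseCategories()],
      confusion = confusion, depthAgreement = depthAgreement,
      miaCertainty = miaCertainty, cdaCertainty = cdaCertainty,
      seed = as.integer(seed))
}

setMethod("show", "SimDesign", function(object) {
  cat(sprintf("SimDesign: %d cases, seed %d, analytic kappa %.3f\n",
              object@nCases, object@seed, analyticKappa(object)))
})

#' Closed-form kappa implied by a design
#'
#' The kappa of the joint category distribution a [SimDesign-class] implies:
#' with truth distribution \eqn{\pi} and misclassification rows \eqn{M},
#' \eqn{p_o = \sum_i \pi_i M_{ii}}, \eqn{p_e = \sum_j \pi_j (\pi^T M)_j} and
#' \eqn{\kappa = (p_o - p_e)/(1 - p_e)}. Estimated kappa from
#' [simulateCases()] output converges to this value as the number of cases
#' grows.
#'
#' @param design a [SimDesign-class].
#' @return numeric(1).
#' @export
setMethod("analyticKappa", "SimDesign", function(design) {
  pi <- design@categoryProbs
  M <- design@confusion
  po <- sum(pi * diag(M))
  miaMarg <- as.numeric(pi %*% M)
  pe <- sum(pi * miaMarg)
  if (pe >= 1 - 1e-12)
    stop("expected agreement is 1, kappa undefined", call. = FALSE)
  (po - pe) / (1 - pe)
})

# category3 codes in a closed block range, in classification order
.expandCategories <- function(start, end) {
  l1 <- substr(start, 1, 1); l2 <- substr(end, 1, 1)
  n1 <- as.integer(substr(start, 2, 3)); n2 <- as.integer(substr(end, 2, 3))
  letters_ <- LETTERS[match(l1, LETTERS):match(l2, LETTERS)]
  unlist(lapply(seq_along(letters_), function(i) {
    lo <- if (i == 1) n1 else 0L
    hi <- if (i == length(letters_)) n2 else 99L
    sprintf("%s%02d", letters_[i], lo:hi)
  }))
}

# per-category pools of blocks under a map (block-level resolution)
.categoryPools <- function(table, map) {
  b <- blockRanges(table)
  b$category <- vapply(seq_len(nrow(b)), function(i) {
    .resolveCategory(b$start[i], b$chapter[i], b$block[i], map)
  }, character(1))
  split(b, b$category)
}

# which coincidence depths a category's pool can realise
.achievableDepths <- function(pool) {
  width <- vapply(seq_len(nrow(pool)),
                  function(i) length(.expandCategories(pool$start[i],
                                                       pool$end[i])),
                  integer(1))
  byChapter <- table(pool$chapter)
  c(perfect = TRUE, almost_perfect = TRUE,
    moderate = any(width >= 2),
    low = any(byChapter >= 2),
    none = length(byChapter) >= 2)
}

.sampleCode <- function(pool, rowIdx = NULL) {
  i <- if (is.null(rowIdx)) sample.int(nrow(pool), 1) else rowIdx
  cat3 <- sample(.expandCategories(pool$start[i], pool$end[i]), 1)
  paste0(cat3, ".", sample(0:9, 1))
}

# draw a (mia, cda) code pair within one category at the requested depth
.codePairAtDepth <- function(pool, depth) {
  switch(depth,
    perfect = {
      code <- .sampleCode(pool)
      c(code, code)
    },
    almost_perfect = {
      i <- sample.int(nrow(pool), 1)
      cat3 <- sample(.expandCategories(pool$start[i], pool$end[i]), 1)
      subs <- sample(0:9, 2)
      paste0(cat3, ".", subs)
    },
    moderate = {
      wide <- which(vapply(seq_len(nrow(pool)), function(i)
        length(.expandCategories(pool$start[i], pool$end[i])) >= 2,
        logical(1)))
      i <- if (length(wide) == 1) wide else sample(wide, 1)
      cats <- sample(.expandCategories(pool$start[i], pool$end[i]), 2)
      paste0(cats, ".", sample(0:9, 2, replace = TRUE))
    },
    low = {
      byCh <- split(seq_len(nrow(pool)), pool$chapter)
      byCh <- byCh[vapply(byCh, length, integer(1)) >= 2]
      ch <- byCh[[if (length(byCh) == 1) 1 else sample(length(byCh), 1)]]
      rows <- sample(ch, 2)
      c(.sampleCode(pool, rows[1]), .sampleCode(pool, rows[2]))
    },
    none = {
      chs <- unique(pool$chapter)
      pick <- sample(chs, 2)
      pickRow <- function(ix) ix[sample.int(length(ix), 1)]  # safe for n = 1
      rows <- c(pickRow(which(pool$chapter == pick[1])),
                pickRow(which(pool$chapter == pick[2])))
      c(.sampleCode(pool, rows[1]), .sampleCode(pool, rows[2]))
    })
}

# grade cells by certainty stratum, coded strata only
.cellsByCertainty <- function() {
  cells <- certaintyMatrixTable()
  split(cells, cells$certainty)
}

#' Generate a synthetic paired-case series
#'
#' Draws `nCases` paired verdicts from a [SimDesign-class]: the CDA (truth)
#' category from `categoryProbs`, the MIA category from the matching
#' misclassification row; for category-concordant pairs an ICD-10 code pair
#' constructed to share exactly the depth sampled from `depthAgreement`
#' (codes are synthesized from the block table, not a real code catalogue);
#' for discordant pairs codes drawn from the two categories' pools in
#' different chapters where possible. Nonconclusive verdicts carry the
#' [nonconclusiveCode()] sentinel and a zero evidence grade; coded verdicts
#' get an evidence grade drawn uniformly from the certainty-matrix cells of a
#' certainty level sampled from the arm's target distribution. A depth that a
#' category's pool cannot realise (e.g. cross-chapter `none` for a
#' single-chapter category) is resampled from the achievable depths,
#' renormalised. Output is deterministic given the design's seed.
#'
#' @param design a [SimDesign-class].
#' @param table a [BlockTable-class].
#' @param map a [CategoryMap-class].
#' @param ... unused.
#' @return A [CaseSet-class] of `nCases` paired verdicts.
#' @examples
#' cs <- simulateCases(simDesign(nCases = 20, seed = 7))
#' cohenKappa(buildConfusionMatrix(cs))
#' @export
setMethod("simulateCases", signature("SimDesign", "BlockTable", "CategoryMap"),
  function(design, table, map, ...) {
    if (exists(".Random.seed", envir = globalenv())) {
      oldSeed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
    }
    set.seed(design@seed)

    cats <- diseaseCategories()
    pools <- .categoryPools(table, map)
    needed <- setdiff(cats, "nonconclusive")
    missing <- setdiff(needed, names(pools))
    if (length(missing))
      stop("no blocks available to sample codes for category: ",
           paste(missing, collapse = ", "), call. = FALSE)
    achievable <- lapply(pools, .achievableDepths)
    depth5 <- c(design@depthAgreement,
                none = 1 - sum(design@depthAgreement))
    cells <- .cellsByCertainty()

    n <- design@nCases
    cdaCat <- sample(cats, n, replace = TRUE, prob = design@categoryProbs)
    miaCat <- vapply(cdaCat, function(cc) {
      sample(cats, 1, prob = design@confusion[match(cc, cats), ])
    }, character(1))

    miaCode <- cdaCode <- character(n)
    for (i in seq_len(n)) {
      mc <- miaCat[i]; cc <- cdaCat[i]
      if (cc == "nonconclusive") cdaCode[i] <- nonconclusiveCode()
      if (mc == "nonconclusive") miaCode[i] <- nonconclusiveCode()
      if (mc == cc && mc != "nonconclusive") {
        pool <- pools[[cc]]
        ok <- achievable[[cc]]
        pr <- depth5 * ok
        if (sum(pr) == 0) stop("no achievable depth for category ", cc)
        depth <- sample(names(depth5), 1, prob = pr / sum(pr))
        pair <- .codePairAtDepth(pool, depth)
        miaCode[i] <- pair[1]; cdaCode[i] <- pair[2]
      } else {
        if (cc != "nonconclusive") {
          cdaCode[i] <- .sampleCode(pools[[cc]])
        }
        if (mc != "nonconclusive") {
          pool <- pools[[mc]]
          if (cc != "nonconclusive") {
            cdaCh <- locateCode(parseIcd10(cdaCode[i]), table)$chapter
            away <- which(pool$chapter != cdaCh)
            if (length(away))
              pool <- pool[away, , drop = FALSE]
          }
          miaCode[i] <- .sampleCode(pool)
        }
      }
    }

    drawGrades <- function(codes, probs) {
      p <- integer(length(codes)); m <- integer(length(codes))
      conc <- rep(NA_character_, length(codes))
      coded <- codes != nonconclusiveCode()
      lev <- character(sum(coded))
      lev <- sample(names(probs), sum(coded), replace = TRUE, prob = probs)
      for (j in seq_along(which(coded))) {
        i <- which(coded)[j]
        stratum <- cells[[lev[j]]]
        row <- stratum[sample.int(nrow(stratum), 1), ]
        p[i] <- row$pathology; m[i] <- row$microbiology
        conc[i] <- row$micro_concordant
      }
      list(p = p, m = m, conc = conc)
    }
    gMia <- drawGrades(miaCode, design@miaCertainty)
    gCda <- drawGrades(cdaCode, design@cdaCertainty)

    certOf <- function(g) as.character(gradeCertainty(
      evidenceGrade(g$p, g$m, g$conc)))

    d <- data.frame(
      case_id = sprintf("sim%03d", seq_len(n)),
      age_months = sample(1:180, n, replace = TRUE),
      sex = sample(c("M", "F"), n, replace = TRUE),
      mia_code = miaCode, mia_chain = "", mia_underlying = "", mia_other = "",
      mia_path_level = gMia$p, mia_micro_level = gMia$m,
      mia_micro_concordant = gMia$conc,
      mia_histo_org_inflam = FALSE, mia_certainty = certOf(gMia),
      cda_code = cdaCode, cda_chain = "", cda_underlying = "", cda_other = "",
      cda_path_level = gCda$p, cda_micro_level = gCda$m,
      cda_micro_concordant = gCda$conc,
      cda_histo_org_inflam = FALSE, cda_certainty = certOf(gCda),
      stringsAsFactors = FALSE)
    new("CaseSet", data = d)
  })

#' @rdname simulateCases-SimDesign-BlockTable-CategoryMap-method
#' @export
setMethod("simulateCases", signature("SimDesign", "missing", "missing"),
  function(design, table, map, ...) {
    simulateCases(design, defaultBlockTable(), defaultCategoryMap(), ...)
  })

#' Read a simulation design from YAML
#'
#' The design file mirrors [simDesign()]'s arguments: scalar `n_cases` and
#' `seed`, mappings `category_probs`, `depth_agreement`, `mia_certainty`,
#' `cda_certainty`, and `confusion` as a list of K rows. Omitted entries keep
#' the defaults.
#'
#' @param path path to a YAML design file.
#' @return A [SimDesign-class].
#' @export
readSimDesign <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$n_cases)) args$nCases <- y$n_cases
  if (!is.null(y$seed)) args$seed <- y$seed
  if (!is.null(y$category_probs))
    args$categoryProbs <- unlist(y$category_probs)[diseaseCategories()]
  if (!is.null(y$confusion))
    args$confusion <- do.call(rbind, y$confusion)
  if (!is.null(y$depth_agreement))
    args$depthAgreement <- unlist(y$depth_agreement)[
      c("perfect", "almost_perfect", "moderate", "low")]
  if (!is.null(y$mia_certainty))
    args$miaCertainty <- unlist(y$mia_certainty)[
      c("low", "moderate", "high", "very_high")]
  if (!is.null(y$cda_certainty))
    args$cdaCertainty <- unlist(y$cda_certainty)[
      c("low", "moderate", "high", "very_high")]
  do.call(simDesign, args)
}
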