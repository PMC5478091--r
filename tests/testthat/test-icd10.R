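test_that("parsing decomposes, normalizes and rejects malformed codes", {
  c1 <- parseIcd10("C83.7")
  expect_equal(c1@letter, "C")
  expect_equal(c1@category3, "C83")
  expect_equal(c1@subcode, "7")

  c2 <- parseIcd10("a41 . 5")
  expect_equal(c2@category3, "A41")
  expect_equal(c2@subcode, "5")
  expect_equal(formatIcd10(c2), "A41.5")

  c3 <- parseIcd10("N12")
  expect_true(is.na(c3@subcode))

  expect_error(parseIcd10("4A1"), "4A1")
  expect_error(parseIcd10(""), "malformed")
  expect_error(parseIcd10("U07.1"), "U07")      # chapter XXII rejected
  expect_error(parseIcd10("A41.5+"), "malformed") # dagger/asterisk rejected
  expect_error(parseIcd10("AB1"), "malformed")
})

test_that("locate finds the unique chapter and block, closed at boundaries", {
  bt <- defaultBlockTable()
  loc <- locateCode(parseIcd10(c("A41", "J15", "B99", "Q24")), bt)
  expect_equal(loc$chapter, c("I", "X", "I", "XVII"))
  expect_equal(loc$block, c("A30-A49", "J09-J18", "B99-B99", "Q20-Q28"))
  # category outside every range
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("chapter\tstart\tend\tlabel", "I\tA00\tA09\tintestinal"), tmp)
  expect_error(locateCode(parseIcd10("A41"), readBlockTable(tmp)),
               "outside all chapter ranges")
})

test_that("locate is consistent: equal categories get identical coordinates", {
  set.seed(11)
  bt <- defaultBlockTable()
  cat3 <- randomCodes(60, withSubcode = FALSE)
  a <- locateCode(parseIcd10(paste0(cat3, ".1")), bt)
  b <- locateCode(parseIcd10(paste0(cat3, ".8")), bt)
  expect_equal(a$chapter, b$chapter)
  expect_equal(a$block, b$block)
})

test_that("block tables with overlapping ranges are rejected", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("chapter\tstart\tend\tlabel",
               "I\tA00\tA49\tx", "I\tA30\tA79\ty"), tmp)
  expect_error(readBlockTable(tmp), "overlap")
})

test_that("coincidence levels follow the five-tier hierarchy rule", {
  bt <- defaultBlockTable()
  lv <- function(a, b) as.character(codeCoincidence(parseIcd10(a),
                                                    parseIcd10(b), bt))
  expect_equal(lv("C83.7", "C83.7"), "perfect")
  expect_equal(lv("N10", "N10"), "perfect")      # both without fourth character
  expect_equal(lv("A41.5", "A41.8"), "almost_perfect")
  expect_equal(lv("A40.1", "A41.5"), "moderate") # same block A30-A49
  expect_equal(lv("A41.5", "B20"), "low")        # chapter I, blocks differ
  expect_equal(lv("A41.5", "J15.9"), "none")     # chapters I vs X
})

test_that("coincidence is symmetric, reflexive-perfect, and depth-monotone", {
  set.seed(42)
  bt <- defaultBlockTable()
  a <- parseIcd10(randomCodes(120))
  b <- parseIcd10(randomCodes(120))
  ab <- codeCoincidence(a, b, bt)
  ba <- codeCoincidence(b, a, bt)
  expect_equal(as.character(ab), as.character(ba))
  expect_true(all(codeCoincidence(a, a, bt) == "perfect"))

  # deeper shared prefix never lowers the level: build pairs at each depth
  base <- parseIcd10("A41.5")
  deeper <- list(parseIcd10("A41.5"),  # full identity
                 parseIcd10("A41.8"),  # category3
                 parseIcd10("A40.1"),  # block
                 parseIcd10("B20"),    # chapter
                 parseIcd10("J15.9"))  # nothing shared
  lv <- vapply(deeper, function(x)
    as.character(codeCoincidence(base, x, bt)), character(1))
  ranks <- match(lv, coincidenceLevels())
  expect_true(all(diff(ranks) <= 0))
  expect_equal(lv[1], "perfect")
  expect_equal(lv[5], "none")
})

test_that("categorization resolves category > block > chapter > default", {
  bt <- defaultBlockTable()
  map <- defaultCategoryMap()
  got <- categorizeCode(parseIcd10(c("C83.7", "J15", "Q24", "R99", "I50.0")),
                        map, bt)
  expect_equal(as.character(got),
               c("malignant_tumors", "infectious_diseases",
                 "congenital_malformations", "nonconclusive",
                 "other_diseases"))
  expect_equal(as.character(categorizeCode(nonconclusiveCode(), map, bt)),
               "nonconclusive")

  # an explicit category3 entry overrides its block's assignment
  override <- new("CategoryMap", chapters = map@chapters, blocks = map@blocks,
                  categories = c(J15 = "other_diseases"),
                  default = map@default, strict = TRUE)
  expect_equal(as.character(categorizeCode(parseIcd10("J15.9"), override, bt)),
               "other_diseases")
  expect_equal(as.character(categorizeCode(parseIcd10("J12.0"), override, bt)),
               "infectious_diseases")
})
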