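test_that("predictor categories binarize per the published mapping", {
  expect_equal(binarizeVerdict("polyphen2", "possibly deleterious")$binary,
               "damaging")
  expect_equal(binarizeVerdict("polyphen2", "probably deleterious")$binary,
               "damaging")
  expect_equal(binarizeVerdict("polyphen2", "benign")$binary, "tolerated")
  expect_equal(binarizeVerdict("mutationassessor", "high")$binary, "damaging")
  expect_equal(binarizeVerdict("mutationassessor", "medium")$binary,
               "damaging")
  expect_equal(binarizeVerdict("mutationassessor", "low")$binary, "tolerated")
  expect_equal(binarizeVerdict("mutationassessor", "neutral")$binary,
               "tolerated")
  expect_equal(binarizeVerdict("sift", "damaging")$binary, "damaging")
  expect_equal(binarizeVerdict("condel", "deleterious")$binary, "damaging")
  expect_equal(binarizeVerdict("sift", "")$binary, "unavailable")
  expect_equal(binarizeVerdict("condel", NA)$binary, "unavailable")
  expect_error(binarizeVerdict("cadd", "damaging"), "unknown predictor")
})

test_that("consensus is a majority vote with ties noninformative", {
  v <- function(...) {
    b <- c(...)
    data.frame(tool = c("sift", "polyphen2", "mutationassessor",
                        "condel")[seq_along(b)], binary = b)
  }
  tie <- consensusClassify(v("damaging", "damaging", "tolerated", "tolerated"))
  expect_equal(tie$call, "noninformative")
  expect_equal(tie$concordance, "none")
  full <- consensusClassify(v("damaging", "damaging", "damaging", "damaging"))
  expect_equal(full$call, "damaging")
  expect_equal(full$concordance, "full")
  most <- consensusClassify(v("damaging", "damaging", "damaging", "tolerated"))
  expect_equal(most$call, "damaging")
  expect_equal(most$concordance, "partial")
  # three available with a 2-1 split: majority, partial
  three <- consensusClassify(v("tolerated", "tolerated", "damaging"))
  expect_equal(three$call, "tolerated")
  expect_equal(three$concordance, "partial")
  expect_equal(three$nAvailable, 3)
  # three unanimous is still partial (full is reserved for 4/4)
  three2 <- consensusClassify(v("damaging", "damaging", "damaging"))
  expect_equal(three2$concordance, "partial")
  none <- consensusClassify(v("unavailable", "unavailable"))
  expect_equal(none$call, "noninformative")
  expect_equal(none$nAvailable, 0)
  expect_error(consensusClassify(data.frame(tool = c("sift", "sift"),
                                            binary = "damaging")),
               "duplicate")
})

test_that("consensus is symmetric in tool order", {
  b <- data.frame(tool = c("sift", "polyphen2", "mutationassessor", "condel"),
                  binary = c("damaging", "tolerated", "damaging", "damaging"))
  set.seed(3)
  for (k in 1:5) {
    p <- b[sample(4), ]
    expect_equal(consensusClassify(p), consensusClassify(b))
  }
})

test_that("chi-square matches the closed form and flags the printed bounds", {
  tab <- matrix(c(240, 40, 536, 370), 2)
  r <- chiSquare2x2(tab)
  a <- 240; b <- 536; c <- 40; d <- 370; n <- a + b + c + d
  closed <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(r@chi2, closed, tolerance = 1e-9)
  expect_equal(r@df, 1)
  # independence gives zero statistic and p = 1
  flat <- chiSquare2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat@chi2, 0)
  expect_equal(flat@pValue, 1)
  expect_error(chiSquare2x2(matrix(c(0, 0, 5, 5), 2)), "marginal")
  expect_error(chiSquare2x2(matrix(1:6, 2)), "2x2")
})

test_that("cohort summaries recompute percentages from their own counts", {
  rc <- data.frame(clinical_class = "vus",
                   consensus = c("damaging_full", "tolerated_partial"),
                   n = c(7, 3), n_mapped = c(3, 2), n_damaging = c(2, 0))
  s <- summarizeCohort(makeCohort(rc))
  st <- s@structureTable
  row <- st[st$stratum == "damaging_by_all", ]
  expect_equal(row$n_mapped, 3)
  expect_equal(row$pct_mapped, StructTriage:::roundHalfUp(100 * 3 / 7, 1))
  expect_equal(row$pct_damaging, StructTriage:::roundHalfUp(100 * 2 / 3, 1))
})

test_that("summaries are invariant under record order and empty input", {
  rc <- data.frame(clinical_class = c("vus", "vus", "benign"),
                   consensus = c("damaging_full", "noninformative",
                                 "tolerated_full"),
                   n = c(5, 4, 6), n_mapped = c(2, 1, 0),
                   n_damaging = c(1, 0, 0))
  coh <- makeCohort(rc)
  s1 <- summarizeCohort(coh)
  set.seed(5)
  s2 <- summarizeCohort(coh[sample(nrow(coh)), ])
  expect_equal(s1@structureTable, s2@structureTable)
  expect_equal(s1@predictionTable, s2@predictionTable)
  empty <- summarizeCohort(coh[0, ])
  expect_equal(nrow(empty@predictionTable), 0)
  expect_null(empty@contingency)
})
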