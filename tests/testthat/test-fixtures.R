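test_that("fixture construction is deterministic", {
  for (kind in c("ideal_helix", "beta_hairpin", "disulfide_pair",
                 "cavity_shell")) {
    s1 <- makeStructure(kind)
    s2 <- makeStructure(kind)
    expect_identical(atomTable(s1), atomTable(s2), info = kind)
  }
  j1 <- makeStructure("ideal_helix", jitter = 0.05, seed = 42)
  j2 <- makeStructure("ideal_helix", jitter = 0.05, seed = 42)
  expect_identical(atomTable(j1), atomTable(j2))
  j3 <- makeStructure("ideal_helix", jitter = 0.05, seed = 43)
  expect_false(identical(atomTable(j1), atomTable(j3)))
})

test_that("bridge fixtures place the bridging atoms at the requested distance", {
  ds <- makeStructure("disulfide_pair", d = 2.05)
  sgA <- atomCoordForTest(ds, "SG", 2, "A")
  sgB <- atomCoordForTest(ds, "SG", 2, "B")
  expect_equal(sqrt(sum((sgA - sgB)^2)), 2.05, tolerance = 1e-9)
  expect_equal(nrow(findDisulfides(ds, "A", 2)), 1)
  sb <- makeStructure("salt_bridge_pair", d = 3.7)
  nz <- atomCoordForTest(sb, "NZ", 2, "A")
  od1 <- atomCoordForTest(sb, "OD1", 2, "B")
  expect_equal(sqrt(sum((nz - od1)^2)), 3.7, tolerance = 1e-9)
})

test_that("the extended tripeptide is its own accessibility reference", {
  e <- makeStructure("extended_tripeptide", x = "W")
  expect_equal(relativeSasa(e, "A", 2)$rsaPct, 100, tolerance = 1e-9)
})

test_that("peptide fixtures pass the quality gate with zero outliers", {
  for (kind in c("ideal_helix", "beta_hairpin", "packed_core")) {
    q <- qualityGate(makeStructure(kind))
    expect_equal(length(q$outliers$bond), 0, info = kind)
    expect_equal(length(q$outliers$angle), 0, info = kind)
    expect_equal(length(q$outliers$cbeta), 0, info = kind)
  }
})

test_that("cohort generation validates its counts", {
  expect_error(makeCohort(data.frame(clinical_class = "vus",
                                     consensus = "damaging_full",
                                     n = 3, n_mapped = 5)),
               "inconsistent")
  expect_error(makeCohort(data.frame(clinical_class = "vus",
                                     consensus = "damaging_full",
                                     n = 5, n_mapped = 3, n_damaging = 4)),
               "inconsistent")
  expect_error(makeCohort(data.frame(clinical_class = "vus",
                                     consensus = "sometimes",
                                     n = 1)), "unknown consensus")
  zero <- makeCohort(data.frame(clinical_class = "vus",
                                consensus = "damaging_full", n = 0))
  expect_equal(nrow(zero), 0)
})

test_that("cohorts round-trip through the summary for random count tables", {
  set.seed(20240601)
  strata <- c("damaging_full", "damaging_partial", "noninformative",
              "tolerated_full", "tolerated_partial")
  for (rep in 1:20) {
    n <- sample(0:40, 5, replace = TRUE)
    nm <- vapply(n, function(k) sample(0:k, 1), integer(1))
    nd <- vapply(nm, function(k) sample(0:k, 1), integer(1))
    rc <- data.frame(clinical_class = "vus", consensus = strata,
                     n = n, n_mapped = nm, n_damaging = nd)
    st <- summarizeCohort(makeCohort(rc))@structureTable
    for (i in 1:5) {
      stratum <- c("damaging_by_all", "damaging_by_most", "noninformative",
                   "tolerated_by_all", "tolerated_by_most")[i]
      row <- st[st$stratum == stratum, ]
      expect_equal(row$n_total, n[i], info = stratum)
      expect_equal(row$n_mapped, nm[i], info = stratum)
      expect_equal(row$n_damaging, nd[i], info = stratum)
    }
    tot <- st[st$stratum == "damaging_total", ]
    expect_equal(tot$n_total, n[1] + n[2])
    expect_equal(tot$n_damaging, nd[1] + nd[2])
  }
})
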