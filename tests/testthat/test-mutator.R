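test_that("stripping respects the 5 Angstrom boundary exactly", {
  # two short chains with the closest inter-chain atoms at a set distance
  place <- function(d) {
    a <- buildPeptide("GCG", phi = 180, psi = 180)
    sg <- atomCoordForTest(a, "SG", resno = 2)
    cb <- atomCoordForTest(a, "CB", resno = 2)
    dir <- (sg - cb) / sqrt(sum((sg - cb)^2))
    one <- new("StructureModel", id = "probe", atoms = data.frame(
      chain = "B", resno = 1L, inscode = "", resid = "GLY", elety = "CA",
      elesy = "C", x = sg[1] + d * dir[1], y = sg[2] + d * dir[2],
      z = sg[3] + d * dir[3], o = 1))
    mergeStructuresForTest(a, one)
  }
  atBoundary <- stripEnvironment(place(5.0), "A", 2)
  expect_true(any(atBoundary$strippedSet$chain == "B"))
  beyond <- stripEnvironment(place(5.1), "A", 2)
  expect_false(any(beyond$strippedSet$chain == "B"))
})

test_that("a target with no neighbours strips only itself", {
  iso <- makeStructure("extended_tripeptide", x = "L")
  # residue 3 terminal Gly is within 5 A of residue 2; use a lone residue
  lone <- buildPeptide("A", phi = 180, psi = 180)
  st <- stripEnvironment(lone, "A", 1)
  expect_equal(nrow(st$strippedSet), 1)
  expect_false("CB" %in% atomTable(st$structure)$elety)
})

test_that("the stripped set matches a brute-force all-pairs distance scan", {
  pc <- mkCore("L")
  st <- stripEnvironment(pc, "A", 5)
  a <- atomTable(pc)
  a <- a[a$elesy != "H", ]
  tgt <- a[a$chain == "A" & a$resno == 5, ]
  hit <- character(0)
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(tgt))) {
      d <- sqrt((a$x[i] - tgt$x[j])^2 + (a$y[i] - tgt$y[j])^2 +
                  (a$z[i] - tgt$z[j])^2)
      if (d <= 5.0) hit <- c(hit, paste(a$chain[i], a$resno[i]))
    }
  }
  expected <- sort(unique(hit))
  got <- sort(paste(st$strippedSet$chain, st$strippedSet$resno))
  expect_equal(got, expected)
})

test_that("repacking an unstripped structure with an empty set is identity", {
  h <- makeStructure("ideal_helix", n = 8)
  out <- repackSideChains(h, h@atoms[0, c("chain", "resno", "inscode",
                                          "resid")])
  expect_identical(atomTable(out), atomTable(h))
})

test_that("rebuilt residues carry their full standard heavy-atom complement", {
  pc <- mkCore("L")
  pair <- buildModelPair(pc, "A", 5, mutantAa = "W")
  a <- atomTable(pair@mutant)
  trp <- a[a$chain == "A" & a$resno == 5, ]
  expect_equal(sort(trp$elety),
               sort(c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "NE1",
                      "CE2", "CE3", "CZ2", "CZ3", "CH2")))
  # every rebuilt alanine has exactly N, CA, C, O, CB
  reb <- pair@strippedSet
  for (k in seq_len(nrow(reb))) {
    if (reb$resid[k] != "ALA") next
    ra <- a[a$chain == reb$chain[k] & a$resno == reb$resno[k], ]
    expect_setequal(ra$elety, c("N", "CA", "C", "O", "CB"))
  }
})

test_that("an exposed tryptophan repacks without steric clashes", {
  hx <- makeStructure("ideal_helix", n = 12)
  pair <- buildModelPair(hx, "A", 6, mutantAa = "W")
  ca <- atomCoordForTest(pair@mutant, "CA", resno = 6)
  expect_equal(nrow(clashScoreLocal(pair@mutant, ca)$clashPairs), 0)
})

test_that("the chosen rotamer minimizes overlap among library rotamers", {
  pc <- mkCore("L")
  st <- stripEnvironment(pc, "A", 5)
  packed <- repackSideChains(st$structure, st$strippedSet)
  # exhaustively substitute every library rotamer for the central leucine
  # and verify none beats the chosen one on summed overlap
  rot <- StructTriage:::rotamerLibrary()[["LEU"]]
  aPacked <- atomTable(packed)
  fixed <- aPacked[!(aPacked$chain == "A" & aPacked$resno == 5 &
                       !(aPacked$elety %in% c("N", "CA", "C", "O"))), ]
  f <- list(N = atomCoordForTest(packed, "N", 5),
            CA = atomCoordForTest(packed, "CA", 5),
            C = atomCoordForTest(packed, "C", 5))
  best <- Inf
  for (k in seq_len(nrow(rot))) {
    sc <- StructTriage:::buildSidechainAtoms("LEU", f$N, f$CA, f$C,
                                             as.numeric(rot[k, ]))
    tot <- 0
    for (m in seq_len(nrow(sc))) {
      dd <- sqrt((fixed$x - sc$x[m])^2 + (fixed$y - sc$y[m])^2 +
                   (fixed$z - sc$z[m])^2)
      rr <- StructTriage:::vdwRadius(sc$elesy[m]) +
        StructTriage:::vdwRadius(fixed$elesy)
      ov <- pmax(0, rr - dd)
      ov[fixed$chain == "A" & fixed$resno == 5] <- 0
      tot <- tot + sum(ov)
    }
    best <- min(best, tot)
  }
  # the packed model's own residue overlap is not larger than any rotamer's
  aRes <- aPacked[aPacked$chain == "A" & aPacked$resno == 5 &
                    !(aPacked$elety %in% c("N", "CA", "C", "O")), ]
  tot0 <- 0
  for (m in seq_len(nrow(aRes))) {
    dd <- sqrt((fixed$x - aRes$x[m])^2 + (fixed$y - aRes$y[m])^2 +
                 (fixed$z - aRes$z[m])^2)
    rr <- StructTriage:::vdwRadius(aRes$elesy[m]) +
      StructTriage:::vdwRadius(fixed$elesy)
    ov <- pmax(0, rr - dd)
    ov[fixed$chain == "A" & fixed$resno == 5] <- 0
    tot0 <- tot0 + sum(ov)
  }
  expect_lte(tot0, best + 1e-9)
})

test_that("model pairs keep the backbone exactly and differ only as built", {
  pc <- mkCore("L")
  pair <- buildModelPair(pc, "A", 5, mutantAa = "V")
  expect_equal(kabschRmsd(backboneXyz(pc), backboneXyz(pair@repackedWt)),
               0, tolerance = 1e-12)
  expect_equal(kabschRmsd(backboneXyz(pc), backboneXyz(pair@mutant)),
               0, tolerance = 1e-12)
  # identity job: repacked wild type and mutant are atom-for-atom identical
  idp <- buildModelPair(pc, "A", 5, mutantAa = "L")
  expect_identical(atomTable(idp@repackedWt), atomTable(idp@mutant))
})

test_that("repeated builds of the same job are bit-identical", {
  pc <- mkCore("L")
  p1 <- buildModelPair(pc, "A", 5, mutantAa = "K")
  p2 <- buildModelPair(pc, "A", 5, mutantAa = "K")
  expect_identical(atomTable(p1@repackedWt), atomTable(p2@repackedWt))
  expect_identical(atomTable(p1@mutant), atomTable(p2@mutant))
})

test_that("unknown residue types are rejected by name", {
  h <- makeStructure("ideal_helix", n = 8)
  reb <- data.frame(chain = "A", resno = 4L, inscode = "", resid = "XXX")
  expect_error(repackSideChains(h, reb), "XXX")
})
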