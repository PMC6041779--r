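test_that("a minimal PDB fixture parses into residues and atoms", {
  tf <- writeTempPdb(c(
    pdbAtomLine(1, "N", "GLY", "A", 1, 0, 0, 0),
    pdbAtomLine(2, "CA", "GLY", "A", 1, 1.458, 0, 0),
    pdbAtomLine(3, "C", "GLY", "A", 1, 2.0, 1.4, 0),
    pdbAtomLine(4, "N", "ALA", "A", 2, 3.3, 1.5, 0),
    pdbAtomLine(5, "CA", "ALA", "A", 2, 4.2, 2.6, 0),
    pdbAtomLine(6, "C", "ALA", "A", 2, 5.6, 2.1, 0),
    pdbAtomLine(7, "N", "SER", "A", 3, 6.6, 3.0, 0),
    pdbAtomLine(8, "CA", "SER", "A", 3, 8.0, 2.7, 0),
    pdbAtomLine(9, "C", "SER", "A", 3, 8.9, 3.9, 0)))
  s <- readStructure(tf)
  expect_s4_class(s, "StructureModel")
  expect_equal(nResidues(s), 3)
  expect_equal(residueTable(s)$aa, c("G", "A", "S"))
})

test_that("the same coordinates parse identically from PDB and mmCIF", {
  p <- readStructure(system.file("extdata", "example_helix.pdb",
                                 package = "StructTriage"))
  c <- readStructure(system.file("extdata", "example_helix.cif",
                                 package = "StructTriage"))
  ap <- atomTable(p); ac <- atomTable(c)
  expect_equal(nrow(ap), nrow(ac))
  expect_equal(ap[, c("x", "y", "z")], ac[, c("x", "y", "z")],
               tolerance = 1e-6)
  expect_identical(ap$elety, ac$elety)
  expect_identical(ap$resid, ac$resid)
  expect_equal(expMethod(c), "xray")
  expect_equal(resolutionOf(c), 1.5)
})

test_that("altloc resolution keeps the highest occupancy, tie goes to A", {
  mkalt <- function(o1, o2) writeTempPdb(c(
    pdbAtomLine(1, "CA", "ALA", "A", 1, 1.458, 0, 0, o = o1, alt = "A"),
    pdbAtomLine(2, "CA", "ALA", "A", 1, 1.600, 0.1, 0, o = o2, alt = "B"),
    pdbAtomLine(3, "C", "ALA", "A", 1, 2.009, 1.422, 0)))
  a1 <- atomTable(readStructure(mkalt(0.6, 0.4)))
  expect_equal(a1$x[a1$elety == "CA"], 1.458)
  a2 <- atomTable(readStructure(mkalt(0.4, 0.6)))
  expect_equal(a2$x[a2$elety == "CA"], 1.6)
  a3 <- atomTable(readStructure(mkalt(0.5, 0.5)))
  expect_equal(a3$x[a3$elety == "CA"], 1.458)
})

test_that("waters are removed and MSE normalizes to MET", {
  tf <- writeTempPdb(c(
    pdbAtomLine(1, "CA", "MSE", "A", 1, 0, 0, 0),
    "HETATM    2 SE   MSE A   1       1.800   0.000   0.000  1.00  0.00          SE",
    "HETATM    3  O   HOH A  99      20.000   0.000   0.000  1.00  0.00           O"))
  a <- atomTable(readStructure(tf))
  expect_true(all(a$resid == "MET"))
  expect_false(any(a$resid %in% c("HOH", "MSE")))
  expect_true("SD" %in% a$elety)  # selenium renamed to the sulfur position
})

test_that("parsing then re-serializing preserves atom count and coordinates", {
  s <- makeStructure("ideal_helix", n = 12, sequence = "AVLKDECFGHWM")
  tf <- tempfile(fileext = ".pdb")
  writeStructurePdb(s, tf)
  s2 <- readStructure(tf)
  expect_equal(nrow(atomTable(s2)), nrow(atomTable(s)))
  expect_equal(atomTable(s2)[, c("x", "y", "z")],
               atomTable(s)[, c("x", "y", "z")], tolerance = 1e-3)
})

test_that("unparseable and empty files raise informative errors", {
  tf <- tempfile(fileext = ".pdb")
  writeLines("this is not a pdb", tf)
  expect_error(readStructure(tf))
  tf2 <- writeTempPdb(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O")
  expect_error(readStructure(tf2), "no protein residues")
})

test_that("HGVS p. substitutions parse to one-letter codes and positions", {
  expect_equal(parseHgvsP("p.Gly132Arg"), list(wt = "G", position = 132L,
                                               mut = "R"))
  expect_equal(parseHgvsP("p.Cys568Gly"), list(wt = "C", position = 568L,
                                               mut = "G"))
  expect_equal(parseHgvsP("Leu46Pro")$mut, "P")
  expect_error(parseHgvsP("p.Xyz12Ala"), "unknown amino-acid")
  expect_error(parseHgvsP("g.123A>T"), "malformed")
})

test_that("best-structure selection follows resolution, size and coverage", {
  mk <- function(id, n, res, method = "xray") {
    s <- buildPeptide(strrep("A", n), -57, -47, id = id, method = method,
                      resolution = if (method == "xray") res else NA_real_)
    s
  }
  hi <- mk("hi", 200, 1.9); lo <- mk("lo", 400, 3.1)
  expect_equal(structureId(selectBestStructure(list(hi, lo), 150)), "hi")
  # permutation invariance
  expect_equal(structureId(selectBestStructure(list(lo, hi), 150)), "hi")
  # the 100-residue rule discards the sharper but shorter structure
  small <- mk("small", 80, 1.9); big <- mk("big", 300, 2.5)
  expect_equal(structureId(selectBestStructure(list(small, big), 50)), "big")
  # single covering candidate wins by default
  one <- mk("one", 150, 2.8)
  expect_equal(structureId(selectBestStructure(list(one), 120)), "one")
  # resolutions within 0.05 A: longest coverage wins
  a <- mk("a", 150, 1.90); b <- mk("b", 280, 1.94)
  expect_equal(structureId(selectBestStructure(list(a, b), 100)), "b")
  # x-ray preferred over NMR; no survivor yields NULL, not an error
  nmr <- mk("nmr", 300, NA, method = "nmr")
  expect_equal(structureId(selectBestStructure(list(nmr, big), 150)), "big")
  expect_null(selectBestStructure(list(small), 50))
  expect_null(selectBestStructure(list(big), 999))
})

test_that("variant mapping matches wild type and recovers numbering offsets", {
  hx <- makeStructure("ideal_helix", n = 12, sequence = "AVLKDECFGHWM")
  v <- new("ProteinVariant", accession = "X", position = 7L,
           wtAa = "C", mutAa = "G")
  m <- mapVariantToStructure(v, hx)
  expect_true(m@mapped)
  expect_true(m@wtMatch)
  # wrong wild type is flagged for exclusion
  v2 <- new("ProteinVariant", accession = "X", position = 7L,
            wtAa = "A", mutAa = "G")
  expect_false(mapVariantToStructure(v2, hx)@wtMatch)
  # canonical sequence shifted by +2 recovers the right residue
  v3 <- new("ProteinVariant", accession = "X", position = 9L,
            wtAa = "C", mutAa = "G")
  m3 <- mapVariantToStructure(v3, hx, canonicalSeq = "GGAVLKDECFGHWM")
  expect_true(m3@mapped)
  expect_equal(m3@resno, 7L)
  expect_true(m3@wtMatch)
  # position outside the resolved range is an unmapped result
  v4 <- new("ProteinVariant", accession = "X", position = 99L,
            wtAa = "A", mutAa = "G")
  expect_false(mapVariantToStructure(v4, hx)@mapped)
})
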