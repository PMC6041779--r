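# Each of the eleven rules gets a positive and a negative fixture case.
# Cavity evaluation is skipped (rule 11 reported not evaluable) except in
# the dedicated cavity-rule test, to keep the suite fast.

flagsFor <- function(structure, chain, resno, mutantAa,
                     config = thresholdConfig(), skipCavity = TRUE) {
  pair <- buildModelPair(structure, chain, resno, mutantAa = mutantAa,
                         config = config)
  evaluateVariant(pair, config, skipCavity = skipCavity)
}

test_that("rule 1: burial switch fires when the 9% threshold is crossed", {
  pos <- flagsFor(mkCore("W", radius = 9.0), "A", 5, "G")
  expect_true(pos@flags[["accessibility_switch"]])
  expect_lt(pos@measurements$rsa_wt_pct, 9)
  expect_gte(pos@measurements$rsa_mut_pct, 9)
  neg <- flagsFor(mkCore("L", radius = 8.5), "A", 5, "V")  # stays buried
  expect_false(neg@flags[["accessibility_switch"]])
})

test_that("rule 2: disulfide loss fires on substitution of a bridged Cys", {
  ds <- makeStructure("disulfide_pair", d = 2.05)
  pos <- flagsFor(ds, "A", 2, "S")
  expect_true(pos@flags[["bridge_breakage"]])
  expect_match(pos@measurements$broken_bridge_partners, "disulfide:B2")
  # no bridge in the wild type: nothing to break
  neg <- flagsFor(makeStructure("disulfide_pair", d = 3.4), "A", 2, "S")
  expect_false(neg@flags[["bridge_breakage"]])
})

test_that("rule 2: salt-bridge loss fires when the charge is removed", {
  sb <- makeStructure("salt_bridge_pair", d = 4.9)
  pos <- flagsFor(sb, "A", 2, "M")   # Lys -> Met drops the charge
  expect_true(pos@flags[["bridge_breakage"]])
  expect_match(pos@measurements$broken_bridge_partners, "saltbridge:B2")
  neg <- flagsFor(makeStructure("salt_bridge_pair", d = 5.1), "A", 2, "M")
  expect_false(neg@flags[["bridge_breakage"]])
})

test_that("rule 3: torsion incompatibility fires for glycine-only backbones", {
  s <- buildPeptide("AAGAA", phi = c(-57, -57, 75, -57, -57),
                    psi = c(-47, -47, -65, -47, -47))
  pos <- flagsFor(s, "A", 3, "A")  # Gly at (+75,-65): general class forbids
  expect_true(pos@flags[["disallowed_torsion"]])
  hx <- makeStructure("ideal_helix", n = 12)
  neg <- flagsFor(hx, "A", 6, "V") # helix point fine for both classes
  expect_false(neg@flags[["disallowed_torsion"]])
})

test_that("rule 4: buried charge changes fire for gain, not for neutral swaps", {
  core <- mkCore("L")
  pos <- flagsFor(core, "A", 5, "K")
  expect_true(pos@flags[["buried_charge_change"]])
  neg <- flagsFor(core, "A", 5, "V")
  expect_false(neg@flags[["buried_charge_change"]])
})

test_that("rule 5: a jammed large side chain is a damaging clash", {
  pos <- flagsFor(mkCore("G", radius = 8.5), "A", 5, "W")
  expect_true(pos@flags[["steric_clash"]])
  expect_gte(pos@measurements$clash_mut, 30)
  hx <- makeStructure("ideal_helix", n = 12)
  neg <- flagsFor(hx, "A", 6, "W")  # open site: clash-free rotamer exists
  expect_false(neg@flags[["steric_clash"]])
})

test_that("rule 6: buried hydrophobic to hydrophilic fires per the sets", {
  core <- mkCore("L")
  pos <- flagsFor(core, "A", 5, "Q")
  expect_true(pos@flags[["buried_hydrophobic_to_hydrophilic"]])
  neg <- flagsFor(core, "A", 5, "V")       # hydrophobic to hydrophobic
  expect_false(neg@flags[["buried_hydrophobic_to_hydrophilic"]])
  # threonine is in neither set: the rule does not fire
  neg2 <- flagsFor(core, "A", 5, "T")
  expect_false(neg2@flags[["buried_hydrophobic_to_hydrophilic"]])
})

test_that("rule 7: proline inside a helix or strand disrupts it", {
  hx <- makeStructure("ideal_helix", n = 12)
  pos <- flagsFor(hx, "A", 6, "P")
  expect_true(pos@flags[["proline_in_secondary_structure"]])
  bh <- makeStructure("beta_hairpin")
  pos2 <- flagsFor(bh, "A", 4, "P")        # strand residue (E)
  expect_true(pos2@flags[["proline_in_secondary_structure"]])
  neg <- flagsFor(bh, "A", 6, "P")         # turn residue (T): rule 7 silent
  expect_false(neg@flags[["proline_in_secondary_structure"]])
  expect_true(neg@flags[["substitution_to_proline"]])   # rule 9 still fires
})

test_that("rule 8: buried glycine replacement fires only when buried", {
  pos <- flagsFor(mkCore("G", radius = 8.0), "A", 5, "A")
  expect_true(pos@flags[["buried_glycine_replaced"]])
  hx <- makeStructure("ideal_helix", n = 12, sequence = "AAAAAGAAAAAA")
  neg <- flagsFor(hx, "A", 6, "A")         # surface glycine
  expect_false(neg@flags[["buried_glycine_replaced"]])
})

test_that("rule 9: any substitution to proline fires; others do not", {
  hx <- makeStructure("ideal_helix", n = 12)
  expect_true(flagsFor(hx, "A", 6, "P")@flags[["substitution_to_proline"]])
  expect_false(flagsFor(hx, "A", 6, "K")@flags[["substitution_to_proline"]])
})

test_that("rule 10: glycine in a sharp turn fires on turn codes only", {
  bh <- makeStructure("beta_hairpin")   # Gly 6 and 7 carry T codes
  pos <- flagsFor(bh, "A", 6, "A")
  expect_true(pos@flags[["glycine_in_sharp_turn_replaced"]])
  hx <- makeStructure("ideal_helix", n = 12, sequence = "AAAAAGAAAAAA")
  neg <- flagsFor(hx, "A", 6, "A")      # helical glycine: H, not T/S
  expect_false(neg@flags[["glycine_in_sharp_turn_replaced"]])
})

test_that("rule 11: cavity changes flag at the 70 cubic Angstrom threshold", {
  cs <- makeStructure("cavity_site", volume = 800, x = "W")
  pos <- flagsFor(cs, "A", 2, "G", skipCavity = FALSE)
  expect_true(pos@flags[["cavity_change"]])
  expect_gte(abs(pos@measurements$cavity_delta_A3), 70)
  neg <- flagsFor(cs, "A", 2, "F", skipCavity = FALSE)
  expect_false(neg@flags[["cavity_change"]])
  expect_lt(abs(neg@measurements$cavity_delta_A3), 70)
})

test_that("identity substitutions leave all type-based rules false", {
  core <- mkCore("L")
  fl <- flagsFor(core, "A", 5, "L")
  for (rule in c("accessibility_switch", "bridge_breakage",
                 "buried_charge_change", "steric_clash",
                 "buried_hydrophobic_to_hydrophilic",
                 "proline_in_secondary_structure", "buried_glycine_replaced",
                 "substitution_to_proline", "glycine_in_sharp_turn_replaced")) {
    expect_false(isTRUE(fl@flags[[rule]]), info = rule)
  }
})

test_that("verdicts OR the flags and respect not-evaluable rules", {
  mk <- function(vals) {
    f <- setNames(vals, StructTriage:::RULE_NAMES)
    new("FeatureFlags", flags = f, measurements = list())
  }
  allFalse <- mk(rep(FALSE, 11))
  v <- structuralVerdict(allFalse)
  expect_false(v$damaging)
  expect_length(v$triggered, 0)
  one <- mk(c(TRUE, rep(FALSE, 10)))
  v1 <- structuralVerdict(one)
  expect_true(v1$damaging)
  expect_equal(v1$triggered, "accessibility_switch")
  # NA rules are excluded from the OR, not treated as false alarms
  nas <- mk(c(NA, rep(FALSE, 10)))
  expect_false(structuralVerdict(nas)$damaging)
  expect_equal(structuralVerdict(nas)$notEvaluable, "accessibility_switch")
  allNa <- mk(rep(NA, 11))
  expect_true(is.na(structuralVerdict(allNa)$damaging))
  # monotonicity: adding a triggered flag never turns damaging off
  set.seed(11)
  for (k in 1:25) {
    base <- sample(c(TRUE, FALSE, NA), 11, replace = TRUE)
    v0 <- structuralVerdict(mk(base))
    more <- base
    off <- which(!(more %in% TRUE))
    if (length(off)) more[sample(off, 1)] <- TRUE
    v2 <- structuralVerdict(mk(more))
    if (isTRUE(v0$damaging)) expect_true(v2$damaging)
  }
  # configurable exclusion of a rule from the OR
  vex <- structuralVerdict(one, exclude = "accessibility_switch")
  expect_false(vex$damaging)
})

test_that("a glycine-to-arginine jam mirrors the receptor case studies", {
  # buried glycine near a tight site: arginine cannot avoid overlaps
  pos <- flagsFor(mkCore("G", radius = 8.5), "A", 5, "R")
  expect_true(pos@flags[["steric_clash"]])
  v <- structuralVerdict(pos)
  expect_true(v$damaging)
  expect_true("steric_clash" %in% v$triggered)
})
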