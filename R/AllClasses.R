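#' @import methods
NULL

STANDARD_AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
                  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
                  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
                  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

# Common modified residues normalized to their parent amino acid on input.
MODIFIED_AA_PARENT <- c(MSE = "MET", SEC = "CYS", PYL = "LYS", HYP = "PRO",
                        SEP = "SER", TPO = "THR", PTR = "TYR", CSO = "CYS",
                        MLY = "LYS", M3L = "LYS", KCX = "LYS", CME = "CYS")

#' Experimental or synthetic protein structure
#'
#' Holds one coordinate model as a flat atom table plus experimental metadata.
#' Columns of \code{atoms}: \code{chain}, \code{resno} (author numbering),
#' \code{inscode}, \code{resid} (three-letter code), \code{elety} (atom name),
#' \code{elesy} (element), \code{x}, \code{y}, \code{z}, \code{o} (occupancy).
#'
#' @slot id structure identifier (e.g. a PDB code)
#' @slot method experimental method, one of \code{"xray"}, \code{"nmr"},
#'   \code{"unknown"}
#' @slot resolution resolution in Angstrom (\code{NA} for NMR/unknown)
#' @slot modelIndex coordinate model number (NMR ensembles)
#' @slot atoms atom table as described above
#' @export
setClass("StructureModel",
  representation(id = "character", method = "character",
                 resolution = "numeric", modelIndex = "integer",
                 atoms = "data.frame"),
  prototype(id = "synthetic", method = "unknown", resolution = NA_real_,
            modelIndex = 1L))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "inscode", "resid", "elety", "elesy",
            "x", "y", "z", "o")
  if (!all(need %in% names(a)))
    return(paste("atoms table must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) == 0) return("structure has no atoms")
  if (!all(is.finite(c(a$x, a$y, a$z)))) return("non-finite coordinates")
  if (any(a$o < 0 | a$o > 1, na.rm = TRUE)) return("occupancy outside [0,1]")
  if (!object@method %in% c("xray", "nmr", "unknown"))
    return("method must be xray, nmr or unknown")
  if (!is.na(object@resolution) && object@resolution <= 0)
    return("resolution must be positive when present")
  TRUE
})

#' All numeric thresholds used by the triage rules
#'
#' Defaults are the published values: residues with relative solvent
#' accessibility below 9\% are buried; salt bridges require an inter-group
#' atom distance within 5 Angstrom; disulfides a S-gamma distance within
#' 3.3 Angstrom; a clash is a van der Waals overlap of at least 0.4 Angstrom,
#' scored within a 20 Angstrom sphere, damaging at score >= 30 with a >= 70\%
#' increase; cavity changes flagged at >= 70 cubic Angstrom; structures under
#' 100 residues are not used; the quality gate asks for resolution < 2.0
#' Angstrom, at most 5\% residues with > 4 sigma bond-length/angle outliers
#' and at most 5\% with C-beta deviation > 0.25 Angstrom.
#'
#' @export
setClass("ThresholdConfig",
  representation(rsaBuriedPct = "numeric", saltbridgeMaxA = "numeric",
                 ssbondMaxA = "numeric", stripRadiusA = "numeric",
                 clashOverlapA = "numeric", clashScoreMin = "numeric",
                 clashIncreaseMinPct = "numeric", clashLocalRadiusA = "numeric",
                 cavityDeltaMinA3 = "numeric", minStructureResidues = "numeric",
                 qualityResolutionA = "numeric", qualityOutlierSigma = "numeric",
                 qualityOutlierMaxPct = "numeric", qualityCbDevA = "numeric",
                 sharpTurnCodes = "character"),
  prototype(rsaBuriedPct = 9, saltbridgeMaxA = 5.0, ssbondMaxA = 3.3,
            stripRadiusA = 5.0, clashOverlapA = 0.4, clashScoreMin = 30,
            clashIncreaseMinPct = 70, clashLocalRadiusA = 20,
            cavityDeltaMinA3 = 70, minStructureResidues = 100,
            qualityResolutionA = 2.0, qualityOutlierSigma = 4,
            qualityOutlierMaxPct = 5, qualityCbDevA = 0.25,
            sharpTurnCodes = c("T", "S")))

setValidity("ThresholdConfig", function(object) {
  nums <- c(object@rsaBuriedPct, object@saltbridgeMaxA, object@ssbondMaxA,
            object@stripRadiusA, object@clashOverlapA, object@clashScoreMin,
            object@clashIncreaseMinPct, object@clashLocalRadiusA,
            object@cavityDeltaMinA3, object@minStructureResidues,
            object@qualityResolutionA, object@qualityOutlierSigma,
            object@qualityOutlierMaxPct, object@qualityCbDevA)
  if (any(!is.finite(nums)) || any(nums <= 0))
    return("all thresholds must be positive and finite")
  TRUE
})

#' Construct a ThresholdConfig, optionally overriding defaults
#' @param ... named slot overrides, e.g. \code{rsaBuriedPct = 12}
#' @return a \linkS4class{ThresholdConfig}
#' @examples thresholdConfig(ssbondMaxA = 2.5)
#' @export
thresholdConfig <- function(...) new("ThresholdConfig", ...)

#' One missense substitution with clinical class and predictor verdicts
#'
#' @slot accession protein identifier
#' @slot position 1-based canonical-sequence position
#' @slot wtAa,mutAa one-letter amino-acid codes
#' @slot clinicalClass one of \code{"deleterious"}, \code{"benign"},
#'   \code{"vus"}, \code{"other"}
#' @slot verdicts data.frame with columns \code{tool}, \code{raw},
#'   \code{binary}
#' @export
setClass("ProteinVariant",
  representation(accession = "character", position = "integer",
                 wtAa = "character", mutAa = "character",
                 clinicalClass = "character", verdicts = "data.frame"),
  prototype(clinicalClass = "vus",
            verdicts = data.frame(tool = character(), raw = character(),
                                  binary = character())))

setValidity("ProteinVariant", function(object) {
  if (object@position < 1L) return("position must be >= 1")
  if (!object@wtAa %in% STANDARD_AA3 || !object@mutAa %in% STANDARD_AA3)
    return("wtAa/mutAa must be standard one-letter codes")
  if (object@wtAa == object@mutAa) return("wtAa and mutAa must differ")
  if (!object@clinicalClass %in% c("deleterious", "benign", "vus", "other"))
    return("unknown clinical class")
  TRUE
})

#' Repacked wild-type / mutant model pair sharing one backbone
#'
#' @slot repackedWt wild-type model with stripped side chains rebuilt
#' @slot mutant mutant model built on the identical backbone
#' @slot strippedSet data.frame (\code{chain}, \code{resno}, \code{inscode})
#'   of residues whose side chains were rebuilt
#' @slot chain,resno,inscode the substitution target
#' @slot wtAa,mutAa one-letter codes of the substitution
#' @export
setClass("ModelPair",
  representation(repackedWt = "StructureModel", mutant = "StructureModel",
                 strippedSet = "data.frame", chain = "character",
                 resno = "integer", inscode = "character",
                 wtAa = "character", mutAa = "character"))

#' Outcome of the eleven structural-damage checks
#'
#' \code{flags} is a named logical vector over the eleven rules (\code{NA}
#' marks a rule that could not be evaluated); \code{measurements} holds the
#' supporting numbers (relative accessibilities, clash scores, cavity delta,
#' broken bridge partners).
#' @export
setClass("FeatureFlags",
  representation(flags = "logical", measurements = "list"))

RULE_NAMES <- c("accessibility_switch", "bridge_breakage", "disallowed_torsion",
                "buried_charge_change", "steric_clash",
                "buried_hydrophobic_to_hydrophilic",
                "proline_in_secondary_structure", "buried_glycine_replaced",
                "substitution_to_proline", "glycine_in_sharp_turn_replaced",
                "cavity_change")

setValidity("FeatureFlags", function(object) {
  if (!identical(names(object@flags), RULE_NAMES))
    return("flags must be named by the eleven rules, in canonical order")
  TRUE
})

#' 2x2 contingency chi-square result
#' @slot counts 2x2 integer matrix
#' @slot chi2 Pearson chi-square statistic
#' @slot df degrees of freedom (1)
#' @slot pValue upper-tail p value
#' @slot correct whether the continuity correction was applied
#' @export
setClass("ContingencyResult",
  representation(counts = "matrix", chi2 = "numeric", df = "numeric",
                 pValue = "numeric", correct = "logical"))

setValidity("ContingencyResult", function(object) {
  if (!all(dim(object@counts) == c(2, 2))) return("counts must be 2x2")
  if (object@chi2 < 0) return("chi2 must be >= 0")
  if (object@pValue < 0 || object@pValue > 1) return("p value outside [0,1]")
  TRUE
})

#' Cohort-level report: predictor tables and contingency statistics
#' @slot predictionTable per clinical class, consensus-call counts and
#'   percentages
#' @slot structureTable for VUS records, mapped / structurally-damaging counts
#'   and percentages by consensus stratum
#' @slot contingency \linkS4class{ContingencyResult} for
#'   damaging-vs-tolerated consensus against structural damage (NULL when not
#'   computable)
#' @export
setClass("CohortSummary",
  representation(predictionTable = "data.frame", structureTable = "data.frame",
                 contingency = "ANY"))

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  nres <- nrow(unique(a[, c("chain", "resno", "inscode")]))
  cat(sprintf("StructureModel %s [%s%s] %d chain(s), %d residues, %d atoms\n",
              object@id, object@method,
              if (is.na(object@resolution)) ""
              else sprintf(" %.2f A", object@resolution),
              length(unique(a$chain)), nres, nrow(a)))
})

setMethod("show", "ModelPair", function(object) {
  cat(sprintf("ModelPair %s%d%s %s->%s, %d side chain(s) rebuilt\n",
              object@chain, object@resno, object@inscode,
              object@wtAa, object@mutAa, nrow(object@strippedSet)))
})

setMethod("show", "FeatureFlags", function(object) {
  f <- object@flags
  cat("FeatureFlags:", sum(f, na.rm = TRUE), "triggered,",
      sum(is.na(f)), "not evaluable\n")
  for (n in names(f))
    cat(sprintf("  %-34s %s\n", n,
                if (is.na(f[[n]])) "not evaluable" else f[[n]]))
})

setMethod("show", "ContingencyResult", function(object) {
  cat(sprintf("ContingencyResult chi2 = %.4g (df = %d%s), p = %.3g\n",
              object@chi2, as.integer(object@df),
              if (object@correct) ", Yates" else "", object@pValue))
})

# ---- accessors ----

#' @describeIn StructureModel-class atom table accessor
#' @param x a StructureModel
#' @export
atomTable <- function(x) x@atoms

#' @describeIn StructureModel-class structure identifier
#' @export
structureId <- function(x) x@id

#' @describeIn StructureModel-class experimental resolution (NA for NMR)
#' @export
resolutionOf <- function(x) x@resolution

#' @describeIn StructureModel-class experimental method
#' @export
expMethod <- function(x) x@method

#' One row per residue, in file order
#'
#' @param x a \linkS4class{StructureModel}
#' @return data.frame with \code{chain}, \code{resno}, \code{inscode},
#'   \code{resid}, \code{aa} (one-letter or NA for non-standard)
#' @export
residueTable <- function(x) {
  a <- x@atoms
  key <- paste(a$chain, a$resno, a$inscode, sep = "\r")
  idx <- !duplicated(key)
  r <- data.frame(chain = a$chain[idx], resno = a$resno[idx],
                  inscode = a$inscode[idx], resid = a$resid[idx],
                  stringsAsFactors = FALSE)
  r$aa <- unname(STANDARD_AA3[r$resid])
  r
}

#' Number of residues in a structure
#' @param x a \linkS4class{StructureModel}
#' @export
nResidues <- function(x) nrow(residueTable(x))

# Internal: atoms of one residue
residueAtoms <- function(x, chain, resno, inscode = "") {
  a <- x@atoms
  a[a$chain == chain & a$resno == resno & a$inscode == inscode, , drop = FALSE]
}

# Internal: coordinates of a named atom of one residue (or NULL)
atomCoord <- function(x, chain, resno, inscode, elety) {
  a <- residueAtoms(x, chain, resno, inscode)
  i <- which(a$elety == elety)
  if (length(i) == 0) return(NULL)
  c(a$x[i[1]], a$y[i[1]], a$z[i[1]])
}

heavyAtoms <- function(a) a[a$elesy != "H", , drop = FALSE]
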