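# The eleven structural-damage rules, evaluated on a repacked-WT/mutant
# model pair. Each rule is computed independently; a rule whose geometry
# cannot be resolved reports NA ("not evaluable"), never a silent FALSE.

HYDROPHOBIC_AA <- c("V", "I", "L", "M", "F", "W", "C", "A")
HYDROPHILIC_AA <- c("R", "K", "E", "D", "Q", "N")
CHARGE_OF <- c(D = -1, E = -1, H = +1, K = +1, R = +1)

aaCharge <- function(aa) {
  v <- CHARGE_OF[aa]
  v[is.na(v)] <- 0
  unname(v)
}

#' Evaluate the eleven structural-damage rules on a model pair
#'
#' All rules compare the repacked wild-type model with the mutant model
#' built on the same backbone: (1) buried/exposed switch at the relative-
#' accessibility threshold; (2) breakage of a salt bridge or disulfide
#' involving the target; (3) backbone torsion disallowed for the mutant
#' residue class but not the wild-type class; (4) charge change of a buried
#' residue; (5) damaging steric clash (score and relative-increase
#' thresholds); (6) buried hydrophobic replaced by hydrophilic; (7) proline
#' introduced inside helix or strand; (8) buried glycine replaced; (9) any
#' substitution to proline; (10) glycine in a sharp turn replaced; (11)
#' cavity-volume change at or above the threshold. Buried status for rules
#' 4, 6 and 8 is taken from the repacked wild-type model.
#'
#' @param pair a \linkS4class{ModelPair}
#' @param config a \linkS4class{ThresholdConfig}
#' @param skipCavity skip the (comparatively expensive) cavity rule and
#'   report it not evaluable (default FALSE)
#' @return a \linkS4class{FeatureFlags}
#' @export
evaluateVariant <- function(pair, config = thresholdConfig(),
                            skipCavity = FALSE) {
  wt <- pair@repackedWt
  mut <- pair@mutant
  ch <- pair@chain; rn <- pair@resno; ic <- pair@inscode
  wtAa <- pair@wtAa; mutAa <- pair@mutAa
  flags <- setNames(rep(NA, length(RULE_NAMES)), RULE_NAMES)
  meas <- list()
  tryRule <- function(name, expr) {
    val <- tryCatch(expr, error = function(e) {
      meas[[paste0(name, "_error")]] <<- conditionMessage(e)
      NA
    })
    flags[[name]] <<- val
  }

  # shared measurements
  rsaWt <- tryCatch(relativeSasa(wt, ch, rn, ic, config),
                    error = function(e) NULL)
  rsaMut <- tryCatch(relativeSasa(mut, ch, rn, ic, config),
                     error = function(e) NULL)
  if (!is.null(rsaWt)) meas$rsa_wt_pct <- rsaWt$rsaPct
  if (!is.null(rsaMut)) meas$rsa_mut_pct <- rsaMut$rsaPct
  buriedWt <- if (is.null(rsaWt)) NA else rsaWt$buried

  tryRule("accessibility_switch", {
    if (is.null(rsaWt) || is.null(rsaMut)) stop("accessibility not resolved")
    rsaWt$buried != rsaMut$buried
  })

  tryRule("bridge_breakage", {
    broken <- character(0)
    if (wtAa == "C") {
      ssWt <- findDisulfides(wt, ch, rn, ic, config)
      if (nrow(ssWt) > 0) {
        if (mutAa != "C") {
          broken <- c(broken, paste0("disulfide:", ssWt$chain, ssWt$resno,
                                     ssWt$inscode))
        } else {
          ssMut <- findDisulfides(mut, ch, rn, ic, config)
          gone <- !(resKey(ssWt$chain, ssWt$resno, ssWt$inscode) %in%
                      resKey(ssMut$chain, ssMut$resno, ssMut$inscode))
          broken <- c(broken, paste0("disulfide:", ssWt$chain[gone],
                                     ssWt$resno[gone], ssWt$inscode[gone]))
        }
      }
    }
    if (wtAa %in% names(CHARGE_OF)) {
      sbWt <- findSaltBridges(wt, ch, rn, ic, config)
      if (nrow(sbWt) > 0) {
        sbMut <- if (aaCharge(mutAa) == aaCharge(wtAa))
          findSaltBridges(mut, ch, rn, ic, config)
        else data.frame(chain = character(), resno = integer(),
                        inscode = character())
        gone <- !(resKey(sbWt$chain, sbWt$resno, sbWt$inscode) %in%
                    resKey(sbMut$chain, sbMut$resno, sbMut$inscode))
        broken <- c(broken, paste0("saltbridge:", sbWt$chain[gone],
                                   sbWt$resno[gone], sbWt$inscode[gone]))
      }
    }
    meas$broken_bridge_partners <- broken
    length(broken) > 0
  })

  tryRule("disallowed_torsion", {
    tor <- backboneTorsions(wt)
    i <- which(tor$chain == ch & tor$resno == rn & tor$inscode == ic)
    if (length(i) == 0) stop("target torsions not resolved")
    nextIsPro <- i < nrow(tor) && tor$resid[min(i + 1, nrow(tor))] == "PRO"
    phi <- tor$phi[i]; psi <- tor$psi[i]
    meas$phi <- phi; meas$psi <- psi
    dWt <- ramaDisallowed(phi, psi, torsionClassFor(wtAa, nextIsPro))
    dMut <- ramaDisallowed(phi, psi, torsionClassFor(mutAa, nextIsPro))
    if (is.na(dWt) || is.na(dMut)) stop("torsions not evaluable (terminus)")
    dMut && !dWt
  })

  tryRule("buried_charge_change", {
    if (is.na(buriedWt)) stop("burial not resolved")
    buriedWt && aaCharge(wtAa) != aaCharge(mutAa)
  })

  tryRule("steric_clash", {
    caPos <- atomCoord(wt, ch, rn, ic, "CA")
    if (is.null(caPos)) stop("target CA missing")
    clashWt <- clashScoreLocal(wt, caPos, config)
    clashMut <- clashScoreLocal(mut, caPos, config)
    meas$clash_wt <- clashWt$clashScore
    meas$clash_mut <- clashMut$clashScore
    clashDamaging(clashMut, clashWt, config)
  })

  tryRule("buried_hydrophobic_to_hydrophilic", {
    if (is.na(buriedWt)) stop("burial not resolved")
    buriedWt && wtAa %in% HYDROPHOBIC_AA && mutAa %in% HYDROPHILIC_AA
  })

  ssCode <- tryCatch({
    ss <- assignSecondaryStructure(wt)
    i <- which(ss$chain == ch & ss$resno == rn & ss$inscode == ic)
    if (length(i) == 0) NA_character_ else ss$ss[i]
  }, error = function(e) NA_character_)
  meas$ss_wt <- ssCode

  tryRule("proline_in_secondary_structure", {
    if (is.na(ssCode)) stop("secondary structure not resolved")
    mutAa == "P" && ssCode %in% c("H", "G", "I", "E")
  })

  tryRule("buried_glycine_replaced", {
    if (is.na(buriedWt)) stop("burial not resolved")
    wtAa == "G" && buriedWt
  })

  tryRule("substitution_to_proline", mutAa == "P")

  tryRule("glycine_in_sharp_turn_replaced", {
    if (is.na(ssCode)) stop("secondary structure not resolved")
    wtAa == "G" && ssCode %in% config@sharpTurnCodes
  })

  if (!skipCavity) {
    tryRule("cavity_change", {
      cavWt <- cavityVolumes(wt)
      cavMut <- cavityVolumes(mut)
      delta <- cavMut$totalVolume - cavWt$totalVolume
      meas$cavity_wt_A3 <- cavWt$totalVolume
      meas$cavity_mut_A3 <- cavMut$totalVolume
      meas$cavity_delta_A3 <- delta
      abs(delta) >= config@cavityDeltaMinA3
    })
  }
  new("FeatureFlags", flags = flags, measurements = meas)
}

#' Combine feature flags into a structural verdict
#'
#' Damaging iff any evaluable rule fired; rules reported not evaluable are
#' excluded from the disjunction. When no rule could be evaluated the
#' verdict itself is not assessable (\code{damaging = NA}).
#'
#' @param flags a \linkS4class{FeatureFlags}
#' @param exclude rule names to leave out of the disjunction (e.g.
#'   \code{"accessibility_switch"})
#' @return list with \code{damaging} (logical or NA), \code{triggered}
#'   (character vector of rule names), \code{notEvaluable}
#' @export
structuralVerdict <- function(flags, exclude = character(0)) {
  f <- flags@flags
  f <- f[setdiff(names(f), exclude)]
  if (all(is.na(f))) {
    return(list(damaging = NA, triggered = character(0),
                notEvaluable = names(f)))
  }
  list(damaging = any(f, na.rm = TRUE),
       triggered = names(f)[!is.na(f) & f],
       notEvaluable = names(f)[is.na(f)])
}
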