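# Structure quality gate: resolution, covalent-geometry outliers and C-beta
# deviations, with an optional externally supplied MolProbity composite score.

#' Quality-gate a structure for triage
#'
#' Evaluates five criteria: resolution below the threshold (x-ray only);
#' externally supplied MolProbity score below 2.0 (marked not evaluated when
#' absent); at most 5\% of residues with a backbone bond length deviating
#' more than 4 sigma from the ideal-geometry targets; the same for backbone
#' bond angles; and at most 5\% of residues whose observed C-beta lies more
#' than 0.25 Angstrom from the position implied by N, CA and C.
#'
#' @param structure a \linkS4class{StructureModel}
#' @param config a \linkS4class{ThresholdConfig}
#' @param externalMolprobity optional MolProbity composite score (the score
#'   itself is not computed here)
#' @return list with \code{pass} (all evaluable criteria met), and a
#'   \code{criteria} data.frame (\code{criterion}, \code{value}, \code{pass};
#'   \code{pass} is NA for criteria that could not be evaluated)
#' @export
qualityGate <- function(structure, config = thresholdConfig(),
                        externalMolprobity = NULL) {
  r <- residueTable(structure)
  n <- nrow(r)
  getc <- function(i, elety) {
    atomCoord(structure, r$chain[i], r$resno[i], r$inscode[i], elety)
  }
  hasBackbone <- vapply(seq_len(n), function(i) {
    !is.null(getc(i, "N")) && !is.null(getc(i, "CA")) && !is.null(getc(i, "C"))
  }, logical(1))
  if (mean(hasBackbone) < 0.5)
    stop("insufficient geometry: backbone atoms missing in >50% of residues")

  sig <- config@qualityOutlierSigma
  bondOut <- angleOut <- cbOut <- logical(n)
  for (i in which(hasBackbone)) {
    N <- getc(i, "N"); CA <- getc(i, "CA"); C <- getc(i, "C")
    O <- getc(i, "O"); CB <- getc(i, "CB")
    dev <- function(obs, ideal, s) abs(obs - ideal) > sig * s
    b <- c(dev(vnorm(CA - N), IDEAL_BB$b_n_ca, IDEAL_BB$s_b_n_ca),
           dev(vnorm(C - CA), IDEAL_BB$b_ca_c, IDEAL_BB$s_b_ca_c),
           if (!is.null(O)) dev(vnorm(O - C), IDEAL_BB$b_c_o, IDEAL_BB$s_b_c_o))
    a <- dev(bondAngle(N, CA, C), IDEAL_BB$a_n_ca_c, IDEAL_BB$s_a_n_ca_c)
    if (!is.null(O))
      a <- c(a, dev(bondAngle(CA, C, O), IDEAL_BB$a_ca_c_o, IDEAL_BB$s_a_ca_c_o))
    # peptide link to the successor (same chain, consecutive row)
    if (i < n && hasBackbone[i + 1] && r$chain[i + 1] == r$chain[i]) {
      Nn <- getc(i + 1, "N"); CAn <- getc(i + 1, "CA")
      if (vnorm(Nn - C) < 2.5) {
        b <- c(b, dev(vnorm(Nn - C), IDEAL_BB$b_c_n, IDEAL_BB$s_b_c_n))
        a <- c(a, dev(bondAngle(CA, C, Nn), IDEAL_BB$a_ca_c_n,
                      IDEAL_BB$s_a_ca_c_n),
               dev(bondAngle(C, Nn, CAn), IDEAL_BB$a_c_n_ca,
                   IDEAL_BB$s_a_c_n_ca))
      }
    }
    if (!is.null(CB)) {
      tpl <- sidechainTemplates()[[r$resid[i]]]
      cbRow <- if (!is.null(tpl) && "CB" %in% tpl$atom)
        tpl[tpl$atom == "CB", ][1, ] else NULL
      if (!is.null(cbRow))
        b <- c(b, dev(vnorm(CB - CA), cbRow$bond, IDEAL_BB$s_b_ca_cb))
      cbOut[i] <- vnorm(CB - idealCbeta(r$resid[i], N, CA, C)) >
        config@qualityCbDevA
    }
    bondOut[i] <- any(b)
    angleOut[i] <- any(a)
  }
  pctBond <- 100 * sum(bondOut) / n
  pctAngle <- 100 * sum(angleOut) / n
  pctCb <- 100 * sum(cbOut) / n
  resOk <- if (structure@method == "xray" && !is.na(structure@resolution))
    structure@resolution < config@qualityResolutionA else NA
  mpOk <- if (!is.null(externalMolprobity)) externalMolprobity < 2.0 else NA
  criteria <- data.frame(
    criterion = c("resolution", "molprobity", "bond_length_outliers",
                  "bond_angle_outliers", "cbeta_deviation_outliers"),
    value = c(structure@resolution,
              if (is.null(externalMolprobity)) NA_real_ else externalMolprobity,
              pctBond, pctAngle, pctCb),
    pass = c(resOk, mpOk,
             pctBond <= config@qualityOutlierMaxPct,
             pctAngle <= config@qualityOutlierMaxPct,
             pctCb <= config@qualityOutlierMaxPct),
    stringsAsFactors = FALSE)
  list(pass = all(criteria$pass, na.rm = TRUE), criteria = criteria,
       outliers = list(bond = which(bondOut), angle = which(angleOut),
                       cbeta = which(cbOut)))
}
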