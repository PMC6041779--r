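# Secondary-structure assignment: an implementation of the Kabsch-Sander
# hydrogen-bond pattern algorithm (codes H, G, I, E, B, T, S, '-').
# Amide hydrogens are reconstructed geometrically: H sits 1.0 Angstrom from N
# along the direction of the preceding carbonyl C=O bond.

# Backbone coordinate frame per residue, with chain-break detection.
backboneFrame <- function(structure) {
  r <- residueTable(structure)
  n <- nrow(r)
  get <- function(i, elety)
    atomCoord(structure, r$chain[i], r$resno[i], r$inscode[i], elety)
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    for (nm in c("N", "CA", "C", "O")) {
      p <- get(i, nm)
      if (!is.null(p)) {
        switch(nm, N = N[i, ] <- p, CA = CA[i, ] <- p,
               C = C[i, ] <- p, O = O[i, ] <- p)
      }
    }
  }
  hasBB <- rowSums(is.na(cbind(N, CA, C, O))) == 0
  linked <- rep(FALSE, n)  # linked[i]: peptide bond i-1 -> i intact
  if (n > 1) {
    for (i in 2:n) {
      linked[i] <- r$chain[i] == r$chain[i - 1] && hasBB[i] && hasBB[i - 1] &&
        vnorm(N[i, ] - C[i - 1, ]) < 2.5
    }
  }
  list(res = r, N = N, CA = CA, C = C, O = O, hasBB = hasBB, linked = linked)
}

#' Assign secondary structure (Kabsch-Sander algorithm)
#'
#' Computes backbone hydrogen bonds with the electrostatic energy model
#' E = 0.084 (1/rON + 1/rCH - 1/rOH - 1/rCN) * 332 kcal/mol (bond when
#' E < -0.5), then derives n-turns, helices, bridges and ladders, turns and
#' bends per the published pattern rules. Ladder bulges are not bridged, and
#' sheets are not merged into sheet labels; per-residue codes only.
#'
#' @param structure a \linkS4class{StructureModel}
#' @return data.frame with \code{chain}, \code{resno}, \code{inscode},
#'   \code{ss} (one of H, G, I, E, B, T, S, -)
#' @export
assignSecondaryStructure <- function(structure) {
  bb <- backboneFrame(structure)
  r <- bb$res
  n <- nrow(r)
  out <- data.frame(chain = r$chain, resno = r$resno, inscode = r$inscode,
                    ss = rep("-", n), stringsAsFactors = FALSE)
  if (n < 4) return(out)
  # reconstructed amide H (none for prolines or chain starts)
  H <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (bb$linked[i] && r$resid[i] != "PRO") {
      co <- bb$C[i - 1, ] - bb$O[i - 1, ]
      H[i, ] <- bb$N[i, ] + vunit(co)
    }
  }
  # hb[i, j]: C=O of residue i accepts the N-H of residue j
  hb <- matrix(FALSE, n, n)
  q <- 27.888  # 0.42 * 0.20 * 332
  for (j in seq_len(n)) {           # donor j
    if (any(is.na(H[j, ])) || !bb$hasBB[j]) next
    for (i in seq_len(n)) {         # acceptor i
      if (abs(i - j) < 2 || !bb$hasBB[i]) next
      if (vnorm(bb$CA[i, ] - bb$CA[j, ]) > 9) next
      rON <- vnorm(bb$O[i, ] - bb$N[j, ])
      rCH <- vnorm(bb$C[i, ] - H[j, ])
      rOH <- vnorm(bb$O[i, ] - H[j, ])
      rCN <- vnorm(bb$C[i, ] - bb$N[j, ])
      E <- q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      hb[i, j] <- E < -0.5
    }
  }
  # contiguity: residues i..i+k connected without chain break
  contig <- function(i, k) i + k <= n && all(bb$linked[(i + 1):(i + k)])
  turn <- list()
  for (tn in 3:5) {
    t <- rep(FALSE, n)
    for (i in seq_len(n - tn)) t[i] <- contig(i, tn) && hb[i, i + tn]
    turn[[tn]] <- t
  }
  ss <- rep("-", n)
  # bends
  if (n >= 5) {
    for (i in 3:(n - 2)) {
      if (contig(i - 2, 4)) {
        u <- bb$CA[i, ] - bb$CA[i - 2, ]
        v <- bb$CA[i + 2, ] - bb$CA[i, ]
        kappa <- acos(max(-1, min(1, sum(vunit(u) * vunit(v))))) * 180 / pi
        if (kappa > 70) ss[i] <- "S"
      }
    }
  }
  # turns
  for (tn in 3:5) {
    for (i in which(turn[[tn]])) {
      idx <- (i + 1):(i + tn - 1)
      ss[idx][ss[idx] == "-" | ss[idx] == "S"] <- "T"
    }
  }
  # bridges and ladders
  btype <- matrix("", n, n)
  for (i in 2:(n - 1)) {
    if (i + 3 > n - 1) break
    for (j in (i + 3):(n - 1)) {
      if (!bb$hasBB[i] || !bb$hasBB[j]) next
      para <- (hb[j, i - 1] && hb[i + 1, j]) || (hb[i, j - 1] && hb[j + 1, i])
      anti <- (hb[j, i] && hb[i, j]) || (hb[j + 1, i - 1] && hb[i + 1, j - 1])
      if (para) btype[i, j] <- "P"
      else if (anti) btype[i, j] <- "A"
    }
  }
  bridgeRes <- which(apply(btype != "", 1, any) | apply(btype != "", 2, any))
  inLadder <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (btype[i, j] == "") next
      ext <- FALSE
      if (i > 1 && j > 1 && btype[i - 1, j - 1] == btype[i, j]) ext <- TRUE
      if (i < n && j < n && btype[i + 1, j + 1] == btype[i, j]) ext <- TRUE
      if (i > 1 && j < n && btype[i - 1, j + 1] == btype[i, j]) ext <- TRUE
      if (i < n && j > 1 && btype[i + 1, j - 1] == btype[i, j]) ext <- TRUE
      if (ext) inLadder[c(i, j)] <- TRUE
    }
  }
  for (i in bridgeRes) ss[i] <- if (inLadder[i]) "E" else "B"
  # helices (later assignments take precedence: I < G < H)
  markHelix <- function(tn, code) {
    t <- turn[[tn]]
    if (n - tn < 2) return(invisible())
    for (i in 2:(n - tn)) {
      if (t[i - 1] && t[i]) {
        idx <- i:(i + tn - 1)
        ss[idx] <<- code
      }
    }
  }
  markHelix(5, "I")
  markHelix(3, "G")
  markHelix(4, "H")
  out$ss <- ss
  out
}

#' Backbone torsions and torsion residue class
#'
#' Phi/psi in degrees (NA at chain termini or across breaks) and the residue
#' class used for torsion-angle classification: \code{proline},
#' \code{glycine}, \code{pre_proline} (residue preceding a proline) or
#' \code{general}.
#'
#' @param structure a \linkS4class{StructureModel}
#' @return data.frame with \code{chain}, \code{resno}, \code{inscode},
#'   \code{resid}, \code{phi}, \code{psi}, \code{class}
#' @export
backboneTorsions <- function(structure) {
  bb <- backboneFrame(structure)
  r <- bb$res
  n <- nrow(r)
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!bb$hasBB[i]) next
    if (i > 1 && bb$linked[i])
      phi[i] <- torsionAngle(bb$C[i - 1, ], bb$N[i, ], bb$CA[i, ], bb$C[i, ])
    if (i < n && bb$linked[i + 1])
      psi[i] <- torsionAngle(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$N[i + 1, ])
  }
  cls <- rep("general", n)
  cls[r$resid == "GLY"] <- "glycine"
  nextPro <- c(r$resid[-1] == "PRO" & bb$linked[-1], FALSE)
  cls[cls == "general" & nextPro] <- "pre_proline"
  cls[r$resid == "PRO"] <- "proline"
  data.frame(chain = r$chain, resno = r$resno, inscode = r$inscode,
             resid = r$resid, phi = phi, psi = psi, class = cls,
             stringsAsFactors = FALSE)
}
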