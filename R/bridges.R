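# Geometric detection of salt bridges and disulfide bridges.

# Charged side-chain groups: atom sets carrying the formal charge.
CHARGED_GROUPS <- list(
  ASP = list(sign = -1, atoms = c("OD1", "OD2")),
  GLU = list(sign = -1, atoms = c("OE1", "OE2")),
  LYS = list(sign = +1, atoms = "NZ"),
  ARG = list(sign = +1, atoms = c("NE", "NH1", "NH2")),
  HIS = list(sign = +1, atoms = c("ND1", "NE2")))

chargedGroupAtoms <- function(structure, chain, resno, inscode = "") {
  a <- residueAtoms(structure, chain, resno, inscode)
  if (nrow(a) == 0) return(NULL)
  grp <- CHARGED_GROUPS[[a$resid[1]]]
  if (is.null(grp)) return(NULL)
  sel <- a[a$elety %in% grp$atoms, , drop = FALSE]
  if (nrow(sel) == 0) return(NULL)
  list(sign = grp$sign, xyz = as.matrix(sel[, c("x", "y", "z")]))
}

minGroupDistance <- function(xyzA, xyzB) {
  d2 <- outer(rowSums(xyzA^2), rowSums(xyzB^2), `+`) - 2 * xyzA %*% t(xyzB)
  sqrt(max(0, min(d2)))
}

#' Salt-bridge partners of one residue
#'
#' A salt bridge is reported when at least one atom pair between the
#' oppositely charged side-chain groups (Asp/Glu carboxylates versus
#' Lys/Arg/His amines) lies within the distance threshold (default 5
#' Angstrom).
#'
#' @param structure a \linkS4class{StructureModel}
#' @param chain,resno,inscode query residue
#' @param config a \linkS4class{ThresholdConfig}
#' @return data.frame of partners (\code{chain}, \code{resno},
#'   \code{inscode}, \code{resid}, \code{minDist}); zero rows when none
#' @export
findSaltBridges <- function(structure, chain, resno, inscode = "",
                            config = thresholdConfig()) {
  q <- chargedGroupAtoms(structure, chain, resno, inscode)
  empty <- data.frame(chain = character(), resno = integer(),
                      inscode = character(), resid = character(),
                      minDist = numeric(), stringsAsFactors = FALSE)
  if (is.null(q)) return(empty)
  r <- residueTable(structure)
  out <- empty
  for (i in seq_len(nrow(r))) {
    if (r$chain[i] == chain && r$resno[i] == resno &&
          r$inscode[i] == inscode) next
    if (!r$resid[i] %in% names(CHARGED_GROUPS)) next
    p <- chargedGroupAtoms(structure, r$chain[i], r$resno[i], r$inscode[i])
    if (is.null(p) || p$sign == q$sign) next
    d <- minGroupDistance(q$xyz, p$xyz)
    if (d <= config@saltbridgeMaxA + 1e-9) {
      out <- rbind(out, data.frame(chain = r$chain[i], resno = r$resno[i],
                                   inscode = r$inscode[i], resid = r$resid[i],
                                   minDist = d, stringsAsFactors = FALSE))
    }
  }
  out
}

#' Disulfide partners of one residue
#'
#' A disulfide bridge is reported when the query residue is a cysteine whose
#' S-gamma lies within the distance threshold (default 3.3 Angstrom) of
#' another cysteine's S-gamma.
#'
#' @inheritParams findSaltBridges
#' @return data.frame of partner cysteines (\code{chain}, \code{resno},
#'   \code{inscode}, \code{sgDist}); zero rows when none
#' @export
findDisulfides <- function(structure, chain, resno, inscode = "",
                           config = thresholdConfig()) {
  empty <- data.frame(chain = character(), resno = integer(),
                      inscode = character(), sgDist = numeric(),
                      stringsAsFactors = FALSE)
  a <- residueAtoms(structure, chain, resno, inscode)
  if (nrow(a) == 0 || a$resid[1] != "CYS") return(empty)
  sg <- atomCoord(structure, chain, resno, inscode, "SG")
  if (is.null(sg)) return(empty)
  at <- structure@atoms
  cand <- at[at$resid == "CYS" & at$elety == "SG", , drop = FALSE]
  out <- empty
  for (i in seq_len(nrow(cand))) {
    if (cand$chain[i] == chain && cand$resno[i] == resno &&
          cand$inscode[i] == inscode) next
    d <- vnorm(c(cand$x[i], cand$y[i], cand$z[i]) - sg)
    if (d <= config@ssbondMaxA + 1e-9) {
      out <- rbind(out, data.frame(chain = cand$chain[i],
                                   resno = cand$resno[i],
                                   inscode = cand$inscode[i],
                                   sgDist = d, stringsAsFactors = FALSE))
    }
  }
  out
}
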