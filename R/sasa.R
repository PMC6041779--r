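# Solvent-accessible surface area: numerical Shrake-Rupley integration on a
# deterministic golden-angle sphere lattice (no RNG), and relative
# accessibility against an extended Gly-X-Gly reference built in code.

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, H = 1.20)

vdwRadius <- function(elesy) {
  r <- VDW_RADII[toupper(elesy)]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Per-residue solvent-accessible surface area
#'
#' Shrake-Rupley numerical SASA over heavy atoms: each atom surface is
#' sampled on a deterministic spiral lattice inflated by the probe radius;
#' points not occluded by any neighbouring atom sphere count towards the
#' accessible area. Hydrogens are ignored.
#'
#' @param structure a \linkS4class{StructureModel}
#' @param probeRadius probe radius in Angstrom (default 1.4, water)
#' @param nPoints lattice points per atom (default 960)
#' @return data.frame with \code{chain}, \code{resno}, \code{inscode},
#'   \code{resid}, \code{sasa} (Angstrom^2)
#' @export
sasaPerResidue <- function(structure, probeRadius = 1.4, nPoints = 960) {
  a <- heavyAtoms(structure@atoms)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- vdwRadius(a$elesy) + probeRadius
  lattice <- sphereLattice(nPoints)
  n <- nrow(a)
  atomArea <- numeric(n)
  for (i in seq_len(n)) {
    ci <- xyz[i, ]
    d2 <- rowSums(sweep(xyz, 2, ci)^2)
    nb <- which(d2 < (rad[i] + rad)^2 & seq_len(n) != i)
    pts <- sweep(lattice * rad[i], 2, ci, `+`)
    if (length(nb) == 0) {
      frac <- 1
    } else {
      occluded <- rep(FALSE, nPoints)
      for (j in nb) {
        if (all(occluded)) break
        dj2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
        occluded <- occluded | dj2 < rad[j]^2
      }
      frac <- mean(!occluded)
    }
    atomArea[i] <- 4 * pi * rad[i]^2 * frac
  }
  key <- paste(a$chain, a$resno, a$inscode, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(chain = a$chain[first], resno = a$resno[first],
                    inscode = a$inscode[first], resid = a$resid[first],
                    stringsAsFactors = FALSE)
  out$sasa <- as.numeric(tapply(atomArea, factor(key, levels = key[first]),
                                sum))
  full <- residueTable(structure)
  miss <- !(paste(full$chain, full$resno, full$inscode, sep = "\r") %in% key)
  if (any(miss)) {
    warning(sum(miss), " residue(s) without heavy atoms given SASA 0")
    add <- full[miss, c("chain", "resno", "inscode", "resid")]
    add$sasa <- 0
    out <- rbind(out, add)
  }
  rownames(out) <- NULL
  out
}

# Reference maximum SASA of residue type X: the central residue of an
# extended (phi = psi = 180 degrees) Gly-X-Gly tripeptide with an all-trans
# side chain, computed with the same engine and cached per parameter set.
maxSasaReference <- function(aa, probeRadius = 1.4, nPoints = 960) {
  keyname <- sprintf("maxsasa_%s_%g_%d", aa, probeRadius, nPoints)
  hit <- .pkgCache[[keyname]]
  if (!is.null(hit)) return(hit)
  pep <- buildPeptide(paste0("G", aa, "G"), phi = 180, psi = 180,
                      id = "gxg-reference")
  s <- sasaPerResidue(pep, probeRadius, nPoints)
  val <- s$sasa[s$resno == 2]
  assign(keyname, val, envir = .pkgCache)
  val
}

#' Relative solvent accessibility of one residue
#'
#' The residue's absolute SASA divided by that of the same residue type in
#' the extended Gly-X-Gly reference tripeptide, as a percentage. Values can
#' exceed 100\% at chain termini. Residues under the threshold (default 9\%)
#' are classified buried.
#'
#' @param structure a \linkS4class{StructureModel}
#' @param chain,resno,inscode residue selector (author numbering)
#' @param config a \linkS4class{ThresholdConfig}
#' @param sasa optional precomputed result of \code{\link{sasaPerResidue}}
#' @return list with \code{absoluteSasa}, \code{maxSasaRef}, \code{rsaPct},
#'   \code{buried}
#' @export
relativeSasa <- function(structure, chain, resno, inscode = "",
                         config = thresholdConfig(), sasa = NULL) {
  if (is.null(sasa)) sasa <- sasaPerResidue(structure)
  i <- which(sasa$chain == chain & sasa$resno == resno &
               sasa$inscode == inscode)
  if (length(i) == 0) stop("residue not found: ", chain, resno, inscode)
  aa <- STANDARD_AA3[sasa$resid[i[1]]]
  if (is.na(aa)) stop("no accessibility reference for residue type ",
                      sasa$resid[i[1]])
  ref <- maxSasaReference(unname(aa))
  rsa <- 100 * sasa$sasa[i[1]] / ref
  list(absoluteSasa = sasa$sasa[i[1]], maxSasaRef = ref, rsaPct = rsa,
       buried = rsa < config@rsaBuriedPct)
}
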