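# Deterministic synthetic structures and cohorts. Every rule, measurement
# and report in the package is testable offline against these fixtures;
# they are built from the ideal-geometry tables, not downloaded coordinates.

#' Apply a rigid-body transform to a structure
#' @param structure a \linkS4class{StructureModel}
#' @param rot 3x3 rotation matrix
#' @param shift numeric(3) translation
#' @return the transformed \linkS4class{StructureModel}
#' @export
transformStructure <- function(structure, rot = diag(3), shift = c(0, 0, 0)) {
  a <- structure@atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(rot)
  a$x <- xyz[, 1] + shift[1]
  a$y <- xyz[, 2] + shift[2]
  a$z <- xyz[, 3] + shift[3]
  out <- structure
  out@atoms <- a
  out
}

mergeChains <- function(models, chains = LETTERS[seq_along(models)],
                        id = "merged") {
  pieces <- lapply(seq_along(models), function(i) {
    a <- models[[i]]@atoms
    a$chain <- chains[i]
    a
  })
  atoms <- do.call(rbind, pieces)
  rownames(atoms) <- NULL
  new("StructureModel", id = id, method = "xray", resolution = 1.5,
      atoms = atoms)
}

# Closed (or pierced) spherical shell of carbon pseudo-atoms whose
# vdW-bounded void has the requested analytic volume.
shellModel <- function(volume, aperture = NULL) {
  rEff <- (3 * volume / (4 * pi))^(1 / 3)
  rShell <- rEff + 1.70  # void is bounded by the atoms' vdW surface
  npts <- ceiling(4 * pi * rShell^2 / (2.4^2 * sqrt(3) / 2))
  pts <- sphereLattice(npts) * rShell
  if (!is.null(aperture)) {
    capZ <- rShell * cos(asin(min(1, aperture / rShell)))
    pts <- pts[pts[, 3] < capZ, , drop = FALSE]
  }
  atoms <- data.frame(chain = "S", resno = seq_len(nrow(pts)),
                      inscode = "", resid = "GLY", elety = "CA",
                      elesy = "C", x = pts[, 1], y = pts[, 2],
                      z = pts[, 3], o = 1, stringsAsFactors = FALSE)
  new("StructureModel", id = "cavity_shell", method = "xray",
      resolution = 1.5, atoms = atoms)
}

# Orient `mover` so that the unit direction from `fromAtom` to `toAtom`
# becomes -dir, then translate so toAtom lands at `anchor` + d * dir.
placeFacing <- function(mover, fromAtom, toAtom, anchor, dir, d) {
  u <- vunit(toAtom - fromAtom)
  rot <- rotationBetween(u, -dir)
  moved <- transformStructure(mover, rot)
  # recompute the pointer atom after rotation
  newTo <- as.numeric(rot %*% toAtom)
  target <- anchor + d * dir
  transformStructure(moved, diag(3), target - newTo)
}

#' Build a deterministic synthetic structure fixture
#'
#' Kinds: \code{ideal_helix} (alpha torsions -57/-47), \code{beta_hairpin}
#' (two strands joined by a tight turn), \code{packed_core} (a central helix
#' surrounded by six parallel helices, burying the central residue),
#' \code{disulfide_pair} and \code{salt_bridge_pair} (two short chains with
#' the bridging atoms at a requested distance), \code{cavity_shell} (a
#' closed shell of carbon pseudo-atoms enclosing a void of requested
#' small-probe volume, optionally pierced by a channel), and
#' \code{extended_tripeptide} (Gly-X-Gly at phi = psi = 180, the
#' accessibility reference construction).
#'
#' @param kind fixture kind (see Details)
#' @param n residue count (\code{ideal_helix})
#' @param sequence one-letter sequence overriding the kind default
#' @param x central residue type (\code{extended_tripeptide},
#'   \code{packed_core})
#' @param d bridge distance in Angstrom (\code{disulfide_pair},
#'   \code{salt_bridge_pair})
#' @param volume requested void volume in cubic Angstrom
#'   (\code{cavity_shell})
#' @param radius helix-axis spacing in Angstrom (\code{packed_core};
#'   default 8.5, tight enough to bury the central residue)
#' @param aperture channel opening radius in Angstrom (\code{cavity_shell};
#'   NULL = sealed)
#' @param jitter coordinate noise sd in Angstrom (default 0, exact ideal
#'   geometry)
#' @param seed RNG seed, used only when \code{jitter > 0}
#' @return a \linkS4class{StructureModel}
#' @export
makeStructure <- function(kind = c("ideal_helix", "beta_hairpin",
                                   "packed_core", "disulfide_pair",
                                   "salt_bridge_pair", "cavity_shell",
                                   "cavity_site", "extended_tripeptide"),
                          n = 12, sequence = NULL, x = "L", d = 2.05,
                          volume = 150, aperture = NULL, radius = 8.5,
                          jitter = 0, seed = 1) {
  kind <- match.arg(kind)
  s <- switch(kind,
    ideal_helix = {
      seq <- sequence %||% strrep("A", n)
      buildPeptide(seq, phi = -57, psi = -47, id = "ideal_helix")
    },
    extended_tripeptide = {
      buildPeptide(paste0("G", x, "G"), phi = 180, psi = 180,
                   id = "extended_tripeptide")
    },
    beta_hairpin = {
      seq <- sequence %||% "AAAAAGGAAAAA"
      nres <- nchar(seq)
      half <- (nres - 2) / 2
      phi <- c(rep(-120, half), 60, 90, rep(-120, half))
      psi <- c(rep(135, half), 30, 0, rep(135, half))
      buildPeptide(seq, phi = phi, psi = psi, id = "beta_hairpin")
    },
    packed_core = {
      seq <- paste0(strrep("A", 4), x, strrep("A", 4))
      central <- buildPeptide(seq, phi = -57, psi = -47)
      ca <- central@atoms[central@atoms$elety == "CA", ]
      axis <- vunit(c(ca$x[nrow(ca)] - ca$x[1], ca$y[nrow(ca)] - ca$y[1],
                      ca$z[nrow(ca)] - ca$z[1]))
      e1 <- vunit(vcross(axis, if (abs(axis[1]) < 0.9) c(1, 0, 0)
                         else c(0, 1, 0)))
      e2 <- vcross(axis, e1)
      shell <- lapply(0:5, function(k) {
        ang <- k * pi / 3
        off <- radius * (cos(ang) * e1 + sin(ang) * e2)
        transformStructure(buildPeptide(strrep("A", 9), -57, -47),
                           diag(3), off)
      })
      mergeChains(c(list(central), shell), id = "packed_core")
    },
    disulfide_pair = {
      # side chains are built at the rotamer the packer itself selects
      # for this backbone, so a repacked wild type reproduces the
      # construction exactly
      a <- buildPeptide("GCG", phi = 180, psi = 180, chis = list(NULL,
                                                                 c(60)))
      sgA <- atomCoord(a, "A", 2, "", "SG")
      cbA <- atomCoord(a, "A", 2, "", "CB")
      dir <- vunit(sgA - cbA)
      b0 <- buildPeptide("GCG", phi = 180, psi = 180, chis = list(NULL,
                                                                  c(60)))
      sgB <- atomCoord(b0, "A", 2, "", "SG")
      cbB <- atomCoord(b0, "A", 2, "", "CB")
      b <- placeFacing(b0, cbB, sgB, sgA, dir, d)
      mergeChains(list(a, b), id = "disulfide_pair")
    },
    salt_bridge_pair = {
      # packer-stable rotamers for this backbone (see disulfide_pair)
      a <- buildPeptide("GKG", phi = 180, psi = 180,
                        chis = list(NULL, c(60, 180, -60, -60)))
      nz <- atomCoord(a, "A", 2, "", "NZ")
      ce <- atomCoord(a, "A", 2, "", "CE")
      dir <- vunit(nz - ce)
      b0 <- buildPeptide("GDG", phi = 180, psi = 180,
                         chis = list(NULL, c(60, 0)))
      od1 <- atomCoord(b0, "A", 2, "", "OD1")
      cg <- atomCoord(b0, "A", 2, "", "CG")
      b <- placeFacing(b0, cg, od1, nz, dir, d)
      mergeChains(list(a, b), id = "salt_bridge_pair")
    },
    cavity_shell = {
      shellModel(volume, aperture)
    },
    cavity_site = {
      shell <- shellModel(volume, aperture)
      pep <- buildPeptide(paste0("G", x, "G"), phi = 180, psi = 180)
      caMid <- atomCoord(pep, "A", 2, "", "CA")
      pep <- transformStructure(pep, diag(3), -caMid)
      atoms <- rbind(pep@atoms, shell@atoms)
      rownames(atoms) <- NULL
      new("StructureModel", id = "cavity_site", method = "xray",
          resolution = 1.5, atoms = atoms)
    })
  if (jitter > 0) {
    set.seed(seed)
    a <- s@atoms
    a$x <- a$x + stats::rnorm(nrow(a), 0, jitter)
    a$y <- a$y + stats::rnorm(nrow(a), 0, jitter)
    a$z <- a$z + stats::rnorm(nrow(a), 0, jitter)
    s@atoms <- a
  }
  s
}

# predictor raw-category patterns realizing each consensus stratum
COHORT_PATTERNS <- list(
  damaging_full = c(sift = "damaging", polyphen2 = "probably deleterious",
                    mutationassessor = "high", condel = "deleterious"),
  damaging_partial = c(sift = "damaging", polyphen2 = "possibly deleterious",
                       mutationassessor = "medium", condel = "neutral"),
  noninformative = c(sift = "damaging", polyphen2 = "benign",
                     mutationassessor = "neutral", condel = "deleterious"),
  tolerated_full = c(sift = "tolerated", polyphen2 = "benign",
                     mutationassessor = "neutral", condel = "neutral"),
  tolerated_partial = c(sift = "tolerated", polyphen2 = "benign",
                        mutationassessor = "low", condel = "deleterious"))

#' Build a synthetic variant cohort realizing requested marginal counts
#'
#' Each row of \code{rowCounts} requests \code{n} variants of one clinical
#' class and consensus stratum, of which \code{n_mapped} are mapped onto a
#' structure and \code{n_damaging} are structurally damaging. Predictor
#' verdict patterns are fixed per stratum (e.g. a 2-2 split realizes
#' noninformative), identifiers are deterministic, and
#' \code{\link{summarizeCohort}} on the result recovers the requested
#' counts exactly.
#'
#' @param rowCounts data.frame with columns \code{clinical_class},
#'   \code{consensus} (one of \code{damaging_full}, \code{damaging_partial},
#'   \code{noninformative}, \code{tolerated_full}, \code{tolerated_partial}),
#'   \code{n}, and optionally \code{n_mapped}, \code{n_damaging}
#' @param seed kept for interface symmetry; the generator is deterministic
#' @return data.frame of variant records (accession, hgvs_p,
#'   clinical_class, four predictor columns, mapped, struct_damaging)
#' @export
makeCohort <- function(rowCounts, seed = 1) {
  need <- c("clinical_class", "consensus", "n")
  if (!all(need %in% names(rowCounts)))
    stop("rowCounts needs columns: ", paste(need, collapse = ", "))
  if (is.null(rowCounts$n_mapped)) rowCounts$n_mapped <- 0L
  if (is.null(rowCounts$n_damaging)) rowCounts$n_damaging <- 0L
  bad <- rowCounts$n_mapped > rowCounts$n |
    rowCounts$n_damaging > rowCounts$n_mapped | rowCounts$n < 0
  if (any(bad)) stop("inconsistent counts (subtotal exceeds total)")
  unknown <- setdiff(rowCounts$consensus, names(COHORT_PATTERNS))
  if (length(unknown)) stop("unknown consensus stratum: ",
                            paste(unknown, collapse = ", "))
  serial <- 0L
  out <- lapply(seq_len(nrow(rowCounts)), function(i) {
    n <- rowCounts$n[i]
    if (n == 0) return(NULL)
    pat <- COHORT_PATTERNS[[rowCounts$consensus[i]]]
    ids <- serial + seq_len(n)
    serial <<- serial + n
    mapped <- seq_len(n) <= rowCounts$n_mapped[i]
    dmg <- ifelse(mapped, seq_len(n) <= rowCounts$n_damaging[i], NA)
    data.frame(accession = sprintf("SYN%06d", ids),
               hgvs_p = sprintf("p.Ala%dVal", 1 + ids),
               clinical_class = rowCounts$clinical_class[i],
               sift = pat[["sift"]], polyphen2 = pat[["polyphen2"]],
               mutationassessor = pat[["mutationassessor"]],
               condel = pat[["condel"]], mapped = mapped,
               struct_damaging = dmg, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(accession = character(), hgvs_p = character(),
                      clinical_class = character(), sift = character(),
                      polyphen2 = character(), mutationassessor = character(),
                      condel = character(), mapped = logical(),
                      struct_damaging = logical(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
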