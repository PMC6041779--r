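# Ideal-geometry peptide construction and side-chain atom placement.
#
# Backbone bond lengths/angles follow the standard protein stereochemistry
# targets (N-CA 1.458, CA-C 1.525, C-N 1.329, C-O 1.231 Angstrom; N-CA-C
# 111.2, CA-C-N 116.2, C-N-CA 121.7, CA-C-O 120.8 degrees); side-chain
# internal coordinates are read from inst/extdata/sidechain_templates.tsv.

IDEAL_BB <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8,
  s_b_n_ca = 0.019, s_b_ca_c = 0.021, s_b_c_n = 0.014, s_b_c_o = 0.020,
  s_b_ca_cb = 0.021,
  s_a_n_ca_c = 2.8, s_a_ca_c_n = 2.0, s_a_c_n_ca = 1.8, s_a_ca_c_o = 1.7)

.pkgCache <- new.env(parent = emptyenv())

extdataPath <- function(file) {
  p <- system.file("extdata", file, package = "StructTriage")
  if (p == "") stop("missing installed data file: ", file)
  p
}

# Side-chain internal-coordinate templates, keyed by three-letter residue name.
sidechainTemplates <- function() {
  if (is.null(.pkgCache$templates)) {
    t <- utils::read.delim(extdataPath("sidechain_templates.tsv"),
                           comment.char = "#", stringsAsFactors = FALSE)
    .pkgCache$templates <- split(t, t$resname)
  }
  .pkgCache$templates
}

# Backbone-independent rotamer library: residue name -> matrix of chi tuples.
rotamerLibrary <- function() {
  if (is.null(.pkgCache$rotamers)) {
    t <- utils::read.delim(extdataPath("rotamers.tsv"),
                           comment.char = "#", stringsAsFactors = FALSE)
    .pkgCache$rotamers <- split(t[, c("chi1", "chi2", "chi3", "chi4")],
                                t$resname)
  }
  .pkgCache$rotamers
}

aa1to3 <- function(aa) {
  m <- names(STANDARD_AA3)[match(aa, STANDARD_AA3)]
  if (any(is.na(m))) stop("unknown one-letter amino acid code: ",
                          paste(aa[is.na(m)], collapse = ", "))
  m
}

elementOf <- function(elety) {
  # PDB convention: first character of the (left-stripped) atom name
  substr(gsub("^[0-9]*", "", elety), 1, 1)
}

#' Build an ideal-geometry peptide backbone
#'
#' Constructs N, CA, C, O coordinates for a chain with the given backbone
#' torsions and standard bond lengths/angles. \code{phi[1]} is unused;
#' \code{psi[n]} only places the terminal carbonyl oxygen.
#'
#' @param sequence one-letter amino-acid string
#' @param phi,psi backbone torsions in degrees (length 1 or nchar(sequence))
#' @param omega peptide-bond torsion (default 180, trans)
#' @param chain chain identifier
#' @return atom data.frame in \linkS4class{StructureModel} layout (backbone
#'   atoms only; see \code{\link{buildPeptide}} for side chains)
#' @keywords internal
buildBackbone <- function(sequence, phi, psi, omega = 180, chain = "A") {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n); omega <- rep_len(omega, n)
  res3 <- aa1to3(aa)
  Npos <- CApos <- Cpos <- Opos <- matrix(NA_real_, n, 3)
  Npos[1, ] <- c(0, 0, 0)
  CApos[1, ] <- c(IDEAL_BB$b_n_ca, 0, 0)
  ang <- IDEAL_BB$a_n_ca_c * pi / 180
  Cpos[1, ] <- CApos[1, ] +
    IDEAL_BB$b_ca_c * c(-cos(ang), sin(ang), 0)
  if (n > 1) {
    for (i in 2:n) {
      Npos[i, ] <- placeAtom(Npos[i - 1, ], CApos[i - 1, ], Cpos[i - 1, ],
                             IDEAL_BB$b_c_n, IDEAL_BB$a_ca_c_n, psi[i - 1])
      CApos[i, ] <- placeAtom(CApos[i - 1, ], Cpos[i - 1, ], Npos[i, ],
                              IDEAL_BB$b_n_ca, IDEAL_BB$a_c_n_ca, omega[i])
      Cpos[i, ] <- placeAtom(Cpos[i - 1, ], Npos[i, ], CApos[i, ],
                             IDEAL_BB$b_ca_c, IDEAL_BB$a_n_ca_c, phi[i])
    }
  }
  for (i in seq_len(n)) {
    Opos[i, ] <- placeAtom(Npos[i, ], CApos[i, ], Cpos[i, ],
                           IDEAL_BB$b_c_o, IDEAL_BB$a_ca_c_o, psi[i] + 180)
  }
  rows <- lapply(seq_len(n), function(i) {
    data.frame(chain = chain, resno = i, inscode = "", resid = res3[i],
               elety = c("N", "CA", "C", "O"), elesy = c("N", "C", "C", "O"),
               x = c(Npos[i, 1], CApos[i, 1], Cpos[i, 1], Opos[i, 1]),
               y = c(Npos[i, 2], CApos[i, 2], Cpos[i, 2], Opos[i, 2]),
               z = c(Npos[i, 3], CApos[i, 3], Cpos[i, 3], Opos[i, 3]),
               o = 1, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Side-chain atom coordinates for one residue from its backbone N/CA/C and a
# chi-angle vector; returns a data.frame of atom rows (possibly empty for GLY).
buildSidechainAtoms <- function(res3, Npos, CApos, Cpos, chis = numeric(0)) {
  if (res3 == "GLY") {
    return(data.frame(elety = character(0), elesy = character(0),
                      x = numeric(0), y = numeric(0), z = numeric(0)))
  }
  tpl <- sidechainTemplates()[[res3]]
  if (is.null(tpl)) stop("no side-chain template for residue type: ", res3)
  coords <- list(N = Npos, CA = CApos, C = Cpos)
  out <- vector("list", nrow(tpl))
  for (k in seq_len(nrow(tpl))) {
    row <- tpl[k, ]
    tor <- row$tor_value
    if (row$tor_type != "fixed") {
      ci <- as.integer(sub("chi", "", row$tor_type))
      if (ci > length(chis) || is.na(chis[ci]))
        stop(res3, " needs chi", ci, " to place atom ", row$atom)
      tor <- chis[ci] + row$tor_value
    }
    pos <- placeAtom(coords[[row$a1]], coords[[row$a2]], coords[[row$a3]],
                     row$bond, row$angle, tor)
    coords[[row$atom]] <- pos
    out[[k]] <- data.frame(elety = row$atom, elesy = elementOf(row$atom),
                           x = pos[1], y = pos[2], z = pos[3],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Build a full-atom ideal peptide as a StructureModel
#'
#' Backbone from \code{buildBackbone} plus side chains at the requested chi
#' angles (default: all-trans, 180 degrees).
#'
#' @inheritParams buildBackbone
#' @param chis optional list (one numeric vector per residue) of chi angles;
#'   missing entries default to all-trans
#' @param id,method,resolution metadata for the resulting model
#' @return a \linkS4class{StructureModel}
#' @export
buildPeptide <- function(sequence, phi, psi, omega = 180, chain = "A",
                         chis = NULL, id = "peptide", method = "xray",
                         resolution = 1.5) {
  bb <- buildBackbone(sequence, phi, psi, omega, chain)
  aa <- strsplit(sequence, "")[[1]]
  res3 <- aa1to3(aa)
  rows <- list(bb)
  for (i in seq_along(aa)) {
    ra <- bb[bb$resno == i, ]
    Npos <- unlist(ra[ra$elety == "N", c("x", "y", "z")], use.names = FALSE)
    CApos <- unlist(ra[ra$elety == "CA", c("x", "y", "z")], use.names = FALSE)
    Cpos <- unlist(ra[ra$elety == "C", c("x", "y", "z")], use.names = FALSE)
    ch <- if (!is.null(chis) && i <= length(chis) && !is.null(chis[[i]]))
      chis[[i]] else rep(180, 4)
    sc <- buildSidechainAtoms(res3[i], Npos, CApos, Cpos, ch)
    if (nrow(sc) > 0) {
      rows[[length(rows) + 1]] <-
        data.frame(chain = chain, resno = i, inscode = "", resid = res3[i],
                   sc, o = 1, stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)
  ord <- order(atoms$resno)
  atoms <- atoms[ord, ]
  rownames(atoms) <- NULL
  new("StructureModel", id = id, method = method, resolution = resolution,
      atoms = atoms)
}

# Ideal C-beta position from backbone N, CA, C using the residue's template
# internal coordinates (ALA values for residues without a template entry).
idealCbeta <- function(res3, Npos, CApos, Cpos) {
  tpl <- sidechainTemplates()[[res3]]
  if (is.null(tpl) || !"CB" %in% tpl$atom) tpl <- sidechainTemplates()[["ALA"]]
  row <- tpl[tpl$atom == "CB", ][1, ]
  placeAtom(Cpos, Npos, CApos, row$bond, row$angle, row$tor_value)
}
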