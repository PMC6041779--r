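# Torsion-angle (Ramachandran) classification by reference-grid lookup.
# Grids are shipped as flat text files (inst/extdata/rama_<class>.txt):
# 36 rows x 36 columns of characters F (favored), A (allowed), O (outlier /
# disallowed). Row r covers psi in (180 - 10r, 190 - 10r], column c covers
# phi in [-190 + 10c, -180 + 10c); i.e. row 1 is the top psi band (+170,180]
# and column 1 the leftmost phi band [-180,-170).

RAMA_CLASSES <- c("general", "glycine", "proline", "pre_proline")

ramaGrid <- function(class) {
  key <- paste0("rama_", class)
  hit <- .pkgCache[[key]]
  if (!is.null(hit)) return(hit)
  if (!class %in% RAMA_CLASSES) stop("unknown torsion class: ", class)
  lines <- readLines(extdataPath(paste0("rama_", class, ".txt")))
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  g <- do.call(rbind, strsplit(lines, ""))
  stopifnot(nrow(g) == 36, ncol(g) == 36)
  assign(key, g, envir = .pkgCache)
  g
}

#' Classify backbone torsions as favored, allowed or disallowed
#'
#' Looks up (phi, psi) in the shipped 10-degree reference grid for the
#' residue's torsion class. On a bin edge, the more permissive of the
#' adjacent bins is reported.
#'
#' @param phi,psi backbone torsions in degrees; NA yields
#'   \code{"not_evaluable"}
#' @param class one of \code{"general"}, \code{"glycine"}, \code{"proline"},
#'   \code{"pre_proline"}
#' @return one of \code{"favored"}, \code{"allowed"}, \code{"disallowed"},
#'   \code{"not_evaluable"}
#' @examples ramaClass(-60, -45, "general")
#' @export
ramaClass <- function(phi, psi, class = "general") {
  if (is.na(phi) || is.na(psi)) return("not_evaluable")
  g <- ramaGrid(class)
  wrap <- function(x) ((x + 180) %% 360) - 180
  phi <- wrap(phi); psi <- wrap(psi)
  lookup <- function(p, s) {
    col <- pmin(36, pmax(1, floor((p + 180) / 10) + 1))
    row <- pmin(36, pmax(1, floor((180 - s) / 10) + 1))
    g[row, col]
  }
  # sample the bin and, on exact 10-degree edges, its neighbours
  eps <- 1e-9
  cand <- lookup(phi, psi)
  if (abs(phi %% 10) < eps) cand <- c(cand, lookup(wrap(phi - 5), psi))
  if (abs(psi %% 10) < eps) cand <- c(cand, lookup(phi, wrap(psi - 5)))
  rank <- c(F = 1, A = 2, O = 3)
  best <- names(rank)[min(rank[cand])]
  switch(best, F = "favored", A = "allowed", O = "disallowed")
}

# TRUE/FALSE/NA convenience used by the rule set.
ramaDisallowed <- function(phi, psi, class) {
  cl <- ramaClass(phi, psi, class)
  if (cl == "not_evaluable") return(NA)
  cl == "disallowed"
}

# Torsion class for an amino-acid type placed at a position whose successor
# may be proline (the backbone is fixed; only the class map changes).
torsionClassFor <- function(aa, nextIsPro = FALSE) {
  if (aa == "P") return("proline")
  if (aa == "G") return("glycine")
  if (nextIsPro) return("pre_proline")
  "general"
}
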