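# Local steric-clash scoring: van der Waals overlaps >= 0.4 Angstrom among
# heavy atoms within a 20 Angstrom sphere, expressed per 1000 atoms.
# Pairs within three covalent bonds (1-2, 1-3, 1-4) and disulfide-linked
# sulfur pairs are excluded; bonding is inferred from interatomic distances.

# Adjacency list over heavy atoms from covalent-distance criteria.
covalentBonds <- function(a) {
  n <- nrow(a)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  isS <- a$elesy == "S"
  adj <- vector("list", n)
  if (n < 2) return(adj)
  cut2 <- 1.9^2
  for (i in seq_len(n - 1)) {
    d2 <- rowSums(sweep(xyz[(i + 1):n, , drop = FALSE], 2, xyz[i, ])^2)
    lim <- ifelse(isS[i] & isS[(i + 1):n], 2.3^2, cut2)
    js <- which(d2 <= lim) + i
    if (length(js)) {
      adj[[i]] <- c(adj[[i]], js)
      for (j in js) adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

# Atom pairs within graph distance <= depth of each other.
bondedWithin <- function(adj, depth = 3) {
  n <- length(adj)
  excl <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) {
    seen <- i
    frontier <- i
    for (d in seq_len(depth)) {
      frontier <- setdiff(unique(unlist(adj[frontier])), seen)
      if (length(frontier) == 0) break
      seen <- c(seen, frontier)
      for (j in frontier) {
        if (j > i) assign(paste(i, j), TRUE, envir = excl)
      }
    }
  }
  excl
}

#' Local clash report around a point
#'
#' Considers heavy atoms within the local radius (default 20 Angstrom) of
#' \code{center}, counts atom pairs whose van der Waals overlap
#' (r_i + r_j - d) meets the clash threshold (default 0.4 Angstrom), and
#' scores them per 1000 atoms in the sphere.
#'
#' @param structure a \linkS4class{StructureModel}
#' @param center numeric(3) coordinate (typically the target residue's CA)
#' @param config a \linkS4class{ThresholdConfig}
#' @return list with \code{clashPairs} (data.frame of atom indices, names
#'   and overlaps), \code{localAtomCount} and \code{clashScore}
#' @export
clashScoreLocal <- function(structure, center, config = thresholdConfig()) {
  a <- heavyAtoms(structure@atoms)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  keep <- rowSums(sweep(xyz, 2, center)^2) <= config@clashLocalRadiusA^2
  a <- a[keep, , drop = FALSE]
  empty <- data.frame(i = integer(), j = integer(), atomI = character(),
                      atomJ = character(), overlap = numeric())
  if (nrow(a) == 0) {
    return(list(clashPairs = empty, localAtomCount = 0L, clashScore = 0))
  }
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- vdwRadius(a$elesy)
  n <- nrow(a)
  adj <- covalentBonds(a)
  excl <- bondedWithin(adj, 3)
  pairs <- empty
  for (i in seq_len(max(0, n - 1))) {
    js <- (i + 1):n
    d <- sqrt(rowSums(sweep(xyz[js, , drop = FALSE], 2, xyz[i, ])^2))
    ov <- rad[i] + rad[js] - d
    hit <- which(ov >= config@clashOverlapA - 1e-9)
    for (h in hit) {
      j <- js[h]
      if (!is.null(excl[[paste(i, j)]])) next
      pairs <- rbind(pairs, data.frame(
        i = i, j = j,
        atomI = paste0(a$chain[i], a$resno[i], a$inscode[i], ":", a$elety[i]),
        atomJ = paste0(a$chain[j], a$resno[j], a$inscode[j], ":", a$elety[j]),
        overlap = ov[h], stringsAsFactors = FALSE))
    }
  }
  list(clashPairs = pairs, localAtomCount = nrow(a),
       clashScore = 1000 * nrow(pairs) / nrow(a))
}

#' Is a mutant clash report damaging relative to the repacked wild type?
#'
#' TRUE iff the mutant clash score meets the absolute threshold (default 30)
#' and the increase over the repacked wild-type score is at least the
#' relative threshold (default 70\%). A wild-type score of zero with a
#' mutant score over the absolute threshold counts as an unbounded increase
#' and is damaging.
#'
#' @param mutantReport,wtReport results of \code{\link{clashScoreLocal}} on
#'   the same neighbourhood of the mutant and repacked wild-type models
#' @param config a \linkS4class{ThresholdConfig}
#' @return logical
#' @export
clashDamaging <- function(mutantReport, wtReport,
                          config = thresholdConfig()) {
  ms <- mutantReport$clashScore
  ws <- wtReport$clashScore
  if (ms < config@clashScoreMin) return(FALSE)
  if (ws == 0) return(TRUE)
  100 * (ms - ws) / ws >= config@clashIncreaseMinPct
}
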