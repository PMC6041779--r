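# Model-pair construction: strip the target residue's side chain and those
# of every residue with an atom within the strip radius, then rebuild side
# chains on the fixed backbone with a deterministic rotamer search.
# Both the repacked wild type and the mutant are built the same way, so the
# comparison downstream is between models with identical provenance.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

resKey <- function(chain, resno, inscode) paste(chain, resno, inscode, sep = "\r")

#' Strip side chains around a target residue
#'
#' Removes all side-chain atoms (everything beyond the backbone, C-beta
#' included) of the target residue and of every residue having at least one
#' atom within \code{stripRadius} of any atom of the target. Hydrogens are
#' dropped throughout (side chains are rebuilt heavy-atom only).
#'
#' @param structure a \linkS4class{StructureModel}
#' @param chain,resno,inscode target residue
#' @param stripRadius radius in Angstrom (default from the config, 5.0)
#' @return list with \code{structure} (stripped) and \code{strippedSet}
#'   (data.frame \code{chain}, \code{resno}, \code{inscode}, \code{resid}
#'   including the target)
#' @export
stripEnvironment <- function(structure, chain, resno, inscode = "",
                             stripRadius = thresholdConfig()@stripRadiusA) {
  a <- heavyAtoms(structure@atoms)
  tsel <- a$chain == chain & a$resno == resno & a$inscode == inscode
  if (!any(tsel)) stop("target residue not resolved: ", chain, resno, inscode)
  txyz <- as.matrix(a[tsel, c("x", "y", "z")])
  axyz <- as.matrix(a[, c("x", "y", "z")])
  near <- rep(FALSE, nrow(a))
  for (k in seq_len(nrow(txyz))) {
    near <- near | rowSums(sweep(axyz, 2, txyz[k, ])^2) <= stripRadius^2 + 1e-9
  }
  keys <- resKey(a$chain, a$resno, a$inscode)
  stripKeys <- unique(c(keys[near], resKey(chain, resno, inscode)))
  drop <- keys %in% stripKeys & !(a$elety %in% BACKBONE_ATOMS)
  stripped <- a[!drop, , drop = FALSE]
  first <- !duplicated(keys) & keys %in% stripKeys
  set <- data.frame(chain = a$chain[first], resno = a$resno[first],
                    inscode = a$inscode[first], resid = a$resid[first],
                    stringsAsFactors = FALSE)
  rownames(stripped) <- NULL
  out <- structure
  out@atoms <- stripped
  list(structure = out, strippedSet = set)
}

# Overlap objective of a candidate side chain against fixed atoms.
# 1-2/1-3/1-4 interactions through the backbone are excluded by skipping the
# adjacent residues' C/N partners for C-beta.
sidechainOverlap <- function(scXyz, scNames, fixed, fixedXyz, fixedRad,
                             ownKey, prevKey, nextKey, res3 = "") {
  total <- 0
  fKeys <- resKey(fixed$chain, fixed$resno, fixed$inscode)
  for (k in seq_len(nrow(scXyz))) {
    r1 <- vdwRadius(elementOf(scNames[k]))
    skip <- fKeys == ownKey
    if (scNames[k] == "CB") {
      skip <- skip | (fKeys == prevKey & fixed$elety == "C") |
        (fKeys == nextKey & fixed$elety == "N")
    }
    if (res3 == "CYS" && scNames[k] == "SG") {
      # cysteine pairs may bond covalently: S-S contact is not a clash
      skip <- skip | (fixed$resid == "CYS" & fixed$elety == "SG")
    }
    d <- sqrt(rowSums(sweep(fixedXyz, 2, scXyz[k, ])^2))
    ov <- pmax(0, r1 + fixedRad - d)
    ov[skip] <- 0
    total <- total + sum(ov)
  }
  total
}

#' Rebuild side chains on a fixed backbone
#'
#' Deterministic rotamer search: residues are rebuilt greedily in descending
#' side-chain size order; for each residue every rotamer in the shipped
#' library is placed from the backbone N/CA/C frame and the one minimizing
#' the summed van der Waals overlap with all currently fixed atoms is kept
#' (ties resolve to the first rotamer in library order). One refinement
#' sweep re-optimizes each residue with all others in place. The backbone
#' never moves and no randomness is involved.
#'
#' @param structure a (stripped) \linkS4class{StructureModel}
#' @param rebuild data.frame with \code{chain}, \code{resno}, \code{inscode},
#'   \code{resid}: the residues to rebuild and the residue type to build
#'   (the type may differ from the structure's, for mutants)
#' @return a \linkS4class{StructureModel} with rebuilt side chains
#' @export
repackSideChains <- function(structure, rebuild) {
  if (nrow(rebuild) == 0) return(structure)
  lib <- rotamerLibrary()
  tpls <- sidechainTemplates()
  bad <- setdiff(setdiff(unique(rebuild$resid), "GLY"), names(tpls))
  if (length(bad))
    stop("residue type absent from rotamer library: ",
         paste(bad, collapse = ", "))
  a <- structure@atoms
  keys <- resKey(a$chain, a$resno, a$inscode)
  rKeys <- resKey(rebuild$chain, rebuild$resno, rebuild$inscode)
  scCount <- vapply(rebuild$resid, function(r3)
    if (r3 == "GLY") 0L else nrow(tpls[[r3]]), integer(1))
  ord <- order(-scCount, rKeys)
  rebuild <- rebuild[ord, , drop = FALSE]
  rKeys <- rKeys[ord]

  # current side-chain atoms per rebuilt residue (start: none)
  scAtoms <- setNames(vector("list", nrow(rebuild)), rKeys)
  frames <- lapply(seq_len(nrow(rebuild)), function(i) {
    ch <- rebuild$chain[i]; rn <- rebuild$resno[i]; ic <- rebuild$inscode[i]
    list(N = atomCoord(structure, ch, rn, ic, "N"),
         CA = atomCoord(structure, ch, rn, ic, "CA"),
         C = atomCoord(structure, ch, rn, ic, "C"))
  })
  r <- residueTable(structure)
  allKeys <- resKey(r$chain, r$resno, r$inscode)
  neighbourKey <- function(i, off) {
    j <- match(rKeys[i], allKeys) + off
    if (j < 1 || j > length(allKeys)) "" else allKeys[j]
  }

  chooseRotamer <- function(i) {
    res3 <- rebuild$resid[i]
    if (res3 == "GLY") return(NULL)
    f <- frames[[i]]
    if (is.null(f$N) || is.null(f$CA) || is.null(f$C))
      stop("missing backbone frame for ", rKeys[i])
    rot <- lib[[res3]]
    fixedParts <- c(list(a[!(keys %in% rKeys), , drop = FALSE]),
                    scAtoms[setdiff(rKeys, rKeys[i])])
    fixed <- do.call(rbind, fixedParts[!vapply(fixedParts, is.null,
                                               logical(1))])
    fixed <- fixed[fixed$elesy != "H", , drop = FALSE]
    # backbone atoms of every rebuilt residue stay fixed context too
    bbOwn <- a[keys %in% rKeys & a$elety %in% BACKBONE_ATOMS, , drop = FALSE]
    fixed <- rbind(fixed, bbOwn)
    fixedXyz <- as.matrix(fixed[, c("x", "y", "z")])
    fixedRad <- vdwRadius(fixed$elesy)
    best <- NULL; bestScore <- Inf
    for (k in seq_len(nrow(rot))) {
      chis <- as.numeric(rot[k, ])
      sc <- buildSidechainAtoms(res3, f$N, f$CA, f$C, chis)
      scXyz <- as.matrix(sc[, c("x", "y", "z")])
      score <- sidechainOverlap(scXyz, sc$elety, fixed, fixedXyz, fixedRad,
                                rKeys[i], neighbourKey(i, -1),
                                neighbourKey(i, +1), res3)
      if (score < bestScore - 1e-12) {
        bestScore <- score
        best <- sc
      }
    }
    data.frame(chain = rebuild$chain[i], resno = rebuild$resno[i],
               inscode = rebuild$inscode[i], resid = res3,
               best, o = 1, stringsAsFactors = FALSE)
  }

  for (i in seq_len(nrow(rebuild))) scAtoms[[rKeys[i]]] <- chooseRotamer(i)
  for (i in seq_len(nrow(rebuild))) scAtoms[[rKeys[i]]] <- chooseRotamer(i)

  # splice rebuilt side chains after each residue's backbone, file order
  keep <- a[!(keys %in% rKeys) | a$elety %in% BACKBONE_ATOMS, , drop = FALSE]
  # mutant residues: relabel backbone resid to the built type
  kk <- resKey(keep$chain, keep$resno, keep$inscode)
  m <- match(kk, rKeys)
  relabel <- !is.na(m)
  keep$resid[relabel] <- rebuild$resid[m[relabel]]
  pieces <- list()
  for (j in seq_len(nrow(r))) {
    rk <- allKeys[j]
    pieces[[length(pieces) + 1]] <- keep[kk == rk, , drop = FALSE]
    hit <- scAtoms[[rk]]
    if (!is.null(hit)) pieces[[length(pieces) + 1]] <- hit
  }
  atoms <- do.call(rbind, pieces)
  rownames(atoms) <- NULL
  out <- structure
  out@atoms <- atoms
  out
}

#' Build a repacked wild-type / mutant model pair
#'
#' Strips the target environment, rebuilds it once with the original residue
#' types (the repacked wild-type control) and once with the target replaced
#' by the mutant type. Both models share the input backbone exactly.
#'
#' @param structure a \linkS4class{StructureModel}
#' @param chain,resno,inscode target residue
#' @param mutantAa one-letter code of the mutant residue type
#' @param config a \linkS4class{ThresholdConfig}
#' @return a \linkS4class{ModelPair}
#' @export
buildModelPair <- function(structure, chain, resno, inscode = "", mutantAa,
                           config = thresholdConfig()) {
  ra <- residueAtoms(structure, chain, resno, inscode)
  if (nrow(ra) == 0) stop("target residue not resolved: ", chain, resno)
  wt3 <- ra$resid[1]
  wtAa <- unname(STANDARD_AA3[wt3])
  if (is.na(wtAa)) stop("target residue is not a standard amino acid: ", wt3)
  if (!mutantAa %in% STANDARD_AA3) stop("unknown mutant type: ", mutantAa)
  st <- stripEnvironment(structure, chain, resno, inscode,
                         config@stripRadiusA)
  wtBuild <- st$strippedSet
  mutBuild <- st$strippedSet
  tsel <- mutBuild$chain == chain & mutBuild$resno == resno &
    mutBuild$inscode == inscode
  mutBuild$resid[tsel] <- aa1to3(mutantAa)
  wt <- repackSideChains(st$structure, wtBuild)
  mut <- repackSideChains(st$structure, mutBuild)
  wt@id <- paste0(structure@id, "-repackedWT")
  mut@id <- paste0(structure@id, "-mut-", wtAa, resno, mutantAa)
  new("ModelPair", repackedWt = wt, mutant = mut, strippedSet = st$strippedSet,
      chain = chain, resno = as.integer(resno), inscode = inscode,
      wtAa = wtAa, mutAa = mutantAa)
}
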