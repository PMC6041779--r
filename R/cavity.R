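# Cavity detection and volume estimation with a dual-probe grid method:
# space reachable by a small probe (1.4 A) but sealed from bulk solvent by
# a large probe (4.0 A) forms cavities. Connected components use
# 26-connectivity; volumes are measured inside the van der Waals surface as
# the union of small-probe balls over sealed probe centres.

# OR of a logical 3D array with its 26-neighbourhood (separable box dilation).
dilate26 <- function(m) {
  d <- dim(m)
  out <- m
  if (d[1] > 1) {
    out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
  }
  m2 <- out
  if (d[2] > 1) {
    out[, -1, ] <- out[, -1, ] | m2[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] | m2[, -1, ]
  }
  m3 <- out
  if (d[3] > 1) {
    out[, , -1] <- out[, , -1] | m3[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | m3[, , -1]
  }
  out
}

#' Detect cavities and estimate their volumes
#'
#' Grid-based dual-probe method. A grid point can host the small probe when
#' its distance to every atom exceeds that atom's van der Waals radius plus
#' \code{probeIn}, and the large probe analogously with \code{probeOut}.
#' Bulk solvent is the large-probe region connected to the box boundary;
#' solvent exposure then spreads from the bulk by \code{probeOut} through
#' atom-free space (a geodesic dilation, so exposure cannot cross a sealed
#' atomic wall). Small-probe centres that remain unexposed define the
#' cavities; each cavity's volume is the union of the small-probe balls
#' around its centres, clipped to the outside of the van der Waals surface,
#' split into 26-connected components.
#'
#' @param structure a \linkS4class{StructureModel}
#' @param gridSpacing grid step in Angstrom (default 0.6)
#' @param probeIn small probe radius (default 1.4)
#' @param probeOut large probe radius (default 4.0)
#' @return list with \code{volumes} (per cavity, descending, Angstrom^3),
#'   \code{totalVolume}, \code{gridSpacing}
#' @export
cavityVolumes <- function(structure, gridSpacing = 0.6, probeIn = 1.4,
                          probeOut = 4.0) {
  a <- heavyAtoms(structure@atoms)
  emptySet <- list(volumes = numeric(0), totalVolume = 0,
                   gridSpacing = gridSpacing)
  if (nrow(a) <= 3) return(emptySet)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- vdwRadius(a$elesy)
  pad <- max(rad) + probeOut + 2 * gridSpacing
  lo <- apply(xyz, 2, min) - pad
  hi <- apply(xyz, 2, max) + pad
  gx <- seq(lo[1], hi[1], by = gridSpacing)
  gy <- seq(lo[2], hi[2], by = gridSpacing)
  gz <- seq(lo[3], hi[3], by = gridSpacing)
  d <- c(length(gx), length(gy), length(gz))

  # distance to the nearest atom surface, exact up to the large probe and
  # capped beyond; per-atom local block updates keep this O(atoms * block)
  capVal <- probeOut + 2 * gridSpacing
  dmin <- array(capVal, dim = d)
  blockAround <- function(center, reach) {
    i0 <- pmax(1, ceiling((center - reach - lo) / gridSpacing) + 1)
    i1 <- pmin(d, floor((center + reach - lo) / gridSpacing) + 1)
    if (any(i0 > i1)) NULL else list(i0 = i0, i1 = i1)
  }
  for (k in seq_len(nrow(xyz))) {
    b <- blockAround(xyz[k, ], rad[k] + capVal)
    if (is.null(b)) next
    sx <- gx[b$i0[1]:b$i1[1]] - xyz[k, 1]
    sy <- gy[b$i0[2]:b$i1[2]] - xyz[k, 2]
    sz <- gz[b$i0[3]:b$i1[3]] - xyz[k, 3]
    dist <- sqrt(outer(outer(sx^2, sy^2, `+`), sz^2, `+`)) - rad[k]
    blk <- dmin[b$i0[1]:b$i1[1], b$i0[2]:b$i1[2], b$i0[3]:b$i1[3]]
    dmin[b$i0[1]:b$i1[1], b$i0[2]:b$i1[2], b$i0[3]:b$i1[3]] <-
      array(pmin(blk, dist), dim = dim(blk))
  }
  freeSmall <- dmin >= probeIn
  freeLarge <- dmin >= probeOut
  atomFree <- dmin >= 0
  # bulk solvent: large-probe region flood-filled from the box boundary
  bulk <- array(FALSE, dim = d)
  bulk[1, , ] <- freeLarge[1, , ]; bulk[d[1], , ] <- freeLarge[d[1], , ]
  bulk[, 1, ] <- bulk[, 1, ] | freeLarge[, 1, ]
  bulk[, d[2], ] <- bulk[, d[2], ] | freeLarge[, d[2], ]
  bulk[, , 1] <- bulk[, , 1] | freeLarge[, , 1]
  bulk[, , d[3]] <- bulk[, , d[3]] | freeLarge[, , d[3]]
  nBulk <- sum(bulk)
  repeat {
    bulk <- dilate26(bulk) & freeLarge
    nNew <- sum(bulk)
    if (nNew == nBulk) break
    nBulk <- nNew
  }
  # exposure: spread from bulk by probeOut through atom-free space
  exposedMask <- bulk
  for (s in seq_len(max(1L, round(probeOut / gridSpacing)))) {
    exposedMask <- dilate26(exposedMask) & atomFree
  }
  centers <- freeSmall & !exposedMask
  centerIdx <- which(centers)
  if (length(centerIdx) == 0) return(emptySet)
  # cavity region: union of small-probe balls around sealed centres,
  # clipped to the outside of the vdW surface
  cavMask <- array(FALSE, dim = d)
  cIx <- ((centerIdx - 1) %% d[1]) + 1
  cIy <- (((centerIdx - 1) %/% d[1]) %% d[2]) + 1
  cIz <- ((centerIdx - 1) %/% (d[1] * d[2])) + 1
  for (s in seq_along(centerIdx)) {
    ctr <- c(gx[cIx[s]], gy[cIy[s]], gz[cIz[s]])
    b <- blockAround(ctr, probeIn)
    if (is.null(b)) next
    sx <- gx[b$i0[1]:b$i1[1]] - ctr[1]
    sy <- gy[b$i0[2]:b$i1[2]] - ctr[2]
    sz <- gz[b$i0[3]:b$i1[3]] - ctr[3]
    inb <- outer(outer(sx^2, sy^2, `+`), sz^2, `+`) <= probeIn^2
    cavMask[b$i0[1]:b$i1[1], b$i0[2]:b$i1[2], b$i0[3]:b$i1[3]] <-
      cavMask[b$i0[1]:b$i1[1], b$i0[2]:b$i1[2], b$i0[3]:b$i1[3]] | inb
  }
  cavMask <- cavMask & atomFree
  cavIdx <- which(cavMask)
  if (length(cavIdx) == 0) return(emptySet)
  # connected components (26-connectivity) among cavity points
  inCav <- integer(prod(d))
  inCav[cavIdx] <- seq_along(cavIdx)
  comp <- integer(length(cavIdx))
  nxny <- d[1] * d[2]
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  ix <- ((cavIdx - 1) %% d[1]) + 1
  iy <- (((cavIdx - 1) %/% d[1]) %% d[2]) + 1
  iz <- ((cavIdx - 1) %/% nxny) + 1
  label <- 0L
  for (s in seq_along(cavIdx)) {
    if (comp[s] != 0L) next
    label <- label + 1L
    queue <- s
    head <- 1L
    comp[s] <- label
    while (head <= length(queue)) {
      cur <- queue[head]
      head <- head + 1L
      for (k in seq_len(nrow(offs))) {
        jx <- ix[cur] + offs[k, 1]; jy <- iy[cur] + offs[k, 2]
        jz <- iz[cur] + offs[k, 3]
        if (jx < 1 || jx > d[1] || jy < 1 || jy > d[2] ||
              jz < 1 || jz > d[3]) next
        lin <- jx + (jy - 1) * d[1] + (jz - 1) * nxny
        t <- inCav[lin]
        if (t != 0L && comp[t] == 0L) {
          comp[t] <- label
          queue <- c(queue, t)
        }
      }
    }
  }
  vols <- sort(as.numeric(table(comp)) * gridSpacing^3, decreasing = TRUE)
  list(volumes = vols, totalVolume = sum(vols), gridSpacing = gridSpacing)
}
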