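# Elementary 3D geometry shared by the builders and the measurement code.
# Coordinates are plain numeric length-3 vectors or n x 3 matrices, in Angstrom.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalize zero vector")
  a / n
}

#' Bond angle at p2, in degrees
#' @param p1,p2,p3 numeric(3) coordinates
#' @return angle p1-p2-p3 in degrees
#' @keywords internal
bondAngle <- function(p1, p2, p3) {
  u <- vunit(p1 - p2)
  v <- vunit(p3 - p2)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

#' Torsion (dihedral) angle, in degrees in (-180, 180]
#' @param p1,p2,p3,p4 numeric(3) coordinates
#' @keywords internal
torsionAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Place an atom from three reference atoms (natural extension reference frame)
#'
#' Returns the position D such that |C-D| = bond, angle(B,C,D) = angle and
#' torsion(A,B,C,D) = torsion (degrees).
#' @param A,B,C numeric(3) reference coordinates
#' @param bond bond length C-D in Angstrom
#' @param angle bond angle B-C-D in degrees
#' @param torsion torsion A-B-C-D in degrees
#' @keywords internal
placeAtom <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- vunit(C - B)
  n <- vunit(vcross(B - A, bc))
  m <- vcross(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Optimal-superposition RMSD between two coordinate sets
#'
#' Closed-form Kabsch algorithm: centers both sets, rotates the first onto the
#' second with the rotation from the singular value decomposition of the
#' covariance matrix (reflection-corrected), and reports the RMSD after
#' superposition.
#'
#' @param a,b n x 3 coordinate matrices with row-wise correspondence
#' @return RMSD in Angstrom (non-negative)
#' @examples
#' x <- matrix(rnorm(30), ncol = 3)
#' kabschRmsd(x, x)  # 0
#' @export
kabschRmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b) || ncol(a) != 3 || ncol(b) != 3)
    stop("coordinate sets must be n x 3 with equal n")
  if (nrow(a) < 3) stop("at least 3 points are required")
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  h <- crossprod(ac, bc)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  ar <- ac %*% t(rot)
  sqrt(mean(rowSums((ar - bc)^2)))
}

# Rotation matrix taking unit vector u onto unit vector v (Rodrigues).
rotationBetween <- function(u, v) {
  u <- vunit(u); v <- vunit(v)
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # pick any perpendicular axis
    ax <- vunit(vcross(u, if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
    K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
    return(diag(3) + 2 * K %*% K)
  }
  ax <- vcross(u, v)
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  diag(3) + K + K %*% K / (1 + c_)
}

# Deterministic unit sphere lattice (golden-angle spiral), n x 3 matrix.
sphereLattice <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  theta <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(theta), r * sin(theta), z)
}
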