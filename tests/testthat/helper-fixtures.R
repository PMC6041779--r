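# Shared helpers: tiny hand-written PDB files, backbone extraction, bond
# perturbation, and an independent polygon-based torsion-region oracle.

writeTempPdb <- function(lines) {
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), tf)
  tf
}

pdbAtomLine <- function(serial, elety, resid, chain, resno, x, y, z,
                        o = 1.0, alt = " ", elesy = NULL) {
  if (is.null(elesy)) elesy <- substr(elety, 1, 1)
  sprintf("ATOM  %5d %s%-3s%s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f  0.00          %2s",
          serial, ifelse(nchar(elety) >= 4, "", " "), elety, alt, resid,
          chain, resno, x, y, z, o, elesy)
}

backboneXyz <- function(structure) {
  a <- atomTable(structure)
  a <- a[a$elety %in% c("N", "CA", "C", "O"), ]
  a <- a[order(a$chain, a$resno, a$inscode, a$elety), ]
  as.matrix(a[, c("x", "y", "z")])
}

# displace the C atom of `resno` along the CA->C direction by `delta`
stretchCaC <- function(structure, resno, delta) {
  a <- atomTable(structure)
  i <- which(a$resno == resno & a$elety == "C")[1]
  ca <- unlist(a[a$resno == resno & a$elety == "CA", c("x", "y", "z")])[1:3]
  cc <- unlist(a[i, c("x", "y", "z")])
  u <- (cc - ca) / sqrt(sum((cc - ca)^2))
  a[i, c("x", "y", "z")] <- cc + delta * u
  structure@atoms <- a
  structure
}

mkCore <- function(x = "L", radius = 8.5) {
  makeStructure("packed_core", x = x, radius = radius)
}

atomCoordForTest <- function(s, elety, resno = 1, chain = "A") {
  a <- atomTable(s)
  i <- which(a$chain == chain & a$resno == resno & a$elety == elety)[1]
  c(a$x[i], a$y[i], a$z[i])
}

mergeStructuresForTest <- function(a, b) {
  aa <- atomTable(a); ab <- atomTable(b)
  aa$chain <- "A"; ab$chain <- "B"
  atoms <- rbind(aa, ab)
  rownames(atoms) <- NULL
  new("StructureModel", id = "merged", method = "xray", resolution = 1.5,
      atoms = atoms)
}

# Independent torsion-region oracle: the analytic region definitions,
# re-derived here rather than read from the shipped grid files.
oracleInEllipse <- function(phi, psi, c1, c2, r1, r2) {
  ((phi - c1) / r1)^2 + ((psi - c2) / r2)^2 <= 1
}
oracleInBox <- function(phi, psi, p1, p2, s1, s2) {
  phi >= p1 & phi <= p2 & psi >= s1 & psi <= s2
}
oracleGeneralFavored <- function(phi, psi) {
  oracleInBox(phi, psi, -170, -50, 100, 180) |
    oracleInBox(phi, psi, -170, -50, -180, -165) |
    oracleInBox(phi, psi, -140, -45, -70, -10) |
    oracleInEllipse(phi, psi, -63, -43, 45, 40)
}
oracleGeneralAllowed <- function(phi, psi) {
  oracleInBox(phi, psi, -180, -40, -120, 180) |
    oracleInBox(phi, psi, -180, -40, -180, -140) |
    oracleInEllipse(phi, psi, 60, 45, 25, 50)
}
oracleGlycineFavored <- function(phi, psi) {
  oracleGeneralFavored(phi, psi) | oracleGeneralFavored(-phi, -psi) |
    oracleInEllipse(phi, psi, 82, 8, 40, 75) |
    oracleInEllipse(phi, psi, -82, -8, 40, 75)
}
oracleGlycineAllowed <- function(phi, psi) {
  oracleGeneralAllowed(phi, psi) | oracleGeneralAllowed(-phi, -psi) |
    oracleInBox(phi, psi, -180, 180, 150, 180) |
    oracleInBox(phi, psi, -180, 180, -180, -150)
}
oracleProlineFavored <- function(phi, psi) {
  oracleInBox(phi, psi, -85, -45, 110, 180) |
    oracleInBox(phi, psi, -85, -45, -55, -15) |
    oracleInEllipse(phi, psi, -65, 150, 30, 40) |
    oracleInEllipse(phi, psi, -65, -35, 30, 30)
}
oracleProlineAllowed <- function(phi, psi) {
  oracleInBox(phi, psi, -110, -35, 100, 180) |
    oracleInBox(phi, psi, -110, -35, -75, 10) |
    oracleInBox(phi, psi, -110, -35, -180, -170)
}
oraclePreProFavored <- function(phi, psi) {
  oracleInBox(phi, psi, -170, -50, 100, 180) |
    oracleInBox(phi, psi, -170, -50, -180, -165) |
    oracleInBox(phi, psi, -140, -60, -50, -10)
}
oraclePreProAllowed <- function(phi, psi) {
  oracleGeneralAllowed(phi, psi) |
    oracleInEllipse(phi, psi, -130, 75, 50, 50)
}
oracleRamaClass <- function(phi, psi, class) {
  f <- switch(class, general = oracleGeneralFavored,
              glycine = oracleGlycineFavored,
              proline = oracleProlineFavored,
              pre_proline = oraclePreProFavored)
  a <- switch(class, general = oracleGeneralAllowed,
              glycine = oracleGlycineAllowed,
              proline = oracleProlineAllowed,
              pre_proline = oraclePreProAllowed)
  if (f(phi, psi)) "favored" else if (a(phi, psi)) "allowed" else "disallowed"
}
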