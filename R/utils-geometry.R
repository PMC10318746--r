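# Small 3D geometry helpers shared across modules. Coordinates are row
# vectors (n x 3 matrices) throughout.

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rodrigues rotation about unit axis `u` by `theta` radians.
.rotationMatrix <- function(u, theta) {
  u <- .unit(u)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Rotate points (rows of `xyz`) about the axis through `origin` along `u`.
.rotateAbout <- function(xyz, origin, u, theta) {
  R <- .rotationMatrix(u, theta)
  sweep(sweep(xyz, 2, origin) %*% t(R), 2, origin, "+")
}

.angleDeg <- function(a, b, c) {
  # angle at b, degrees
  u <- .unit(a - b); v <- .unit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

.dihedralDeg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
  m1 <- .cross(n1, .unit(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Place an atom X from internal coordinates: distance to p1, angle at p1
# with p2, and dihedral such that .dihedralDeg(p3, p2, p1, X) equals
# dihedralDeg (the conventions of the two functions are kept in sync;
# see the placement/measurement round-trip test).
.placeInternal <- function(p1, p2, p3, bond, angleDeg, dihedralDeg) {
  ang <- angleDeg * pi / 180
  dih <- dihedralDeg * pi / 180
  b1 <- .unit(p1 - p2)
  n <- .unit(.cross(p2 - p3, b1))
  m <- .cross(n, b1)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(dih),
         -bond * sin(ang) * sin(dih))
  p1 + d[1] * b1 + d[2] * m + d[3] * n
}

.xyzMatrix <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}

.setXyz <- function(atoms, xyz) {
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

# All pairwise distances between the rows of two coordinate matrices.
.crossDist <- function(a, b) {
  a2 <- rowSums(a * a); b2 <- rowSums(b * b)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
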