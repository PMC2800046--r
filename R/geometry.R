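# Low-level 3D geometry: rotations, dihedrals, internal-coordinate atom
# placement (NeRF) and least-squares superposition.  All angles in degrees,
# all lengths in Angstrom.  Coordinate sets are n x 3 matrices of row vectors.

DEG <- pi / 180

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix about an axis
#'
#' Right-handed rotation by `angle` degrees about the direction `axis`
#' (Rodrigues form). Points transform as row vectors: `x %*% t(R)`.
#'
#' @param axis numeric length-3 direction (need not be unit length).
#' @param angle rotation angle in degrees.
#' @return 3x3 orthonormal rotation matrix.
#' @keywords internal
rotationMatrix <- function(axis, angle) {
  u <- unitv(axis)
  th <- angle * DEG
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

# Rotate rows of X about the line through `point` with direction `axis`.
rotateAbout <- function(X, point, axis, angle) {
  R <- rotationMatrix(axis, angle)
  x <- X[, 1] - point[1]; y <- X[, 2] - point[2]; z <- X[, 3] - point[3]
  cbind(x * R[1, 1] + y * R[1, 2] + z * R[1, 3] + point[1],
        x * R[2, 1] + y * R[2, 2] + z * R[2, 3] + point[2],
        x * R[3, 1] + y * R[3, 2] + z * R[3, 3] + point[3])
}

# Uniform random rotation matrix (random unit quaternion).
randomRotation <- function() {
  q <- stats::rnorm(4)
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# Rotation angle (degrees) of a rotation matrix.
rotationAngle <- function(R) {
  tr <- max(-1, min(3, sum(diag(R))))
  acos((tr - 1) / 2) / DEG
}

#' Dihedral angle of four points
#'
#' Signed torsion a-b-c-d in degrees, IUPAC convention (cis = 0, values in
#' (-180, 180]).
#'
#' @param a,b,c,d numeric length-3 coordinates.
#' @return angle in degrees.
#' @keywords internal
dihedral4 <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- -atan2(y, x) / DEG
  if (ang <= -180) ang <- ang + 360
  ang
}

# Bond angle a-b-c in degrees.
bondAngle3 <- function(a, b, c) {
  u <- unitv(a - b); v <- unitv(c - b)
  acos(max(-1, min(1, sum(u * v)))) / DEG
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Returns the position `d` with bond length |c-d| = `bond`, bond angle
#' b-c-d = `angle` and dihedral a-b-c-d = `torsion` (degrees).
#'
#' @param a,b,c reference coordinates.
#' @param bond,angle,torsion internal coordinates (Angstrom / degrees).
#' @keywords internal
placeAtom <- function(a, b, c, bond, angle, torsion) {
  th <- angle * DEG
  ph <- torsion * DEG
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(th),
          bond * sin(th) * cos(ph),
          bond * sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the rotation `R` and translation `t` minimizing the rmsd of
#' `P %*% t(R) + t` onto `Q` (determinant-corrected, proper rotation only).
#'
#' @param P,Q n x 3 matrices of matched coordinates (P is mobile).
#' @return list with `R` (3x3), `t` (length 3), and `rmsd` after the fit.
#' @export
kabsch <- function(P, Q) {
  stopifnot(is.matrix(P), is.matrix(Q), all(dim(P) == dim(Q)), ncol(P) == 3)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- t(Pc) %*% Qc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cq - as.numeric(R %*% cp)
  fitted <- sweep(P %*% t(R), 2, t, FUN = "+")
  list(R = R, t = t, rmsd = rmsdCoords(fitted, Q))
}

# Apply a kabsch() fit to an arbitrary coordinate set.
applyFit <- function(X, fit) sweep(X %*% t(fit$R), 2, fit$t, FUN = "+")

#' Root-mean-square deviation of two matched coordinate sets
#'
#' @param P,Q n x 3 matrices, rows matched. No superposition is performed.
#' @return rmsd in Angstrom.
#' @export
rmsdCoords <- function(P, Q) {
  stopifnot(all(dim(P) == dim(Q)))
  sqrt(mean(rowSums((P - Q)^2)))
}
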