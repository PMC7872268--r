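# Low-level vector geometry: angles, dihedrals, NeRF atom placement,
# axis-angle rotations. Positions are numeric length-3 vectors or n x 3
# matrices; angles are radians throughout.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Bond angle at b formed by points a-b-c
#' @param a,b,c length-3 numeric vectors.
#' @return angle in radians in `[0, pi]`.
#' @keywords internal
bond_angle <- function(a, b, c) {
  u <- unitv(a - b)
  v <- unitv(c - b)
  acos(max(-1, min(1, sum(u * v))))
}

#' Dihedral angle of four points
#'
#' Signed torsion a-b-c-d about the b-c axis, IUPAC sign convention.
#' @param a,b,c,d length-3 numeric vectors.
#' @return angle in radians in `(-pi, pi]`.
#' @export
dihedral <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x)
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Given three placed atoms `a`, `b`, `c`, returns the position `d` with
#' `|d - c| = bond`, angle b-c-d = `angle` and dihedral a-b-c-d = `dih`.
#'
#' @param a,b,c length-3 numeric vectors of the three reference atoms.
#' @param bond bond length in Angstrom.
#' @param angle bond angle b-c-d in radians.
#' @param dih dihedral a-b-c-d in radians.
#' @return length-3 numeric position.
#' @export
place_atom <- function(a, b, c, bond, angle, dih) {
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(angle),
          bond * sin(angle) * cos(dih),
          -bond * sin(angle) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Rotation matrix for rotation about an axis
#' @param axis length-3 direction (need not be unit).
#' @param theta rotation angle in radians (right-hand rule).
#' @return 3x3 rotation matrix.
#' @keywords internal
rotation_about_axis <- function(axis, theta) {
  u <- unitv(axis)
  ct <- cos(theta)
  st <- sin(theta)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  ct * diag(3) + st * ux + (1 - ct) * (u %o% u)
}

# Rotate rows of matrix m about the axis through point p with direction u.
rotate_points <- function(m, p, u, theta) {
  R <- rotation_about_axis(u, theta)
  sweep(sweep(m, 2, p) %*% t(R), 2, p, `+`)
}

# Wrap angle(s) to (-pi, pi].
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi
  y
}

#' Circular difference of two angles in degrees
#' @param a,b angles in degrees.
#' @return absolute difference in `[0, 180]`.
#' @keywords internal
circ_diff_deg <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

# Pairwise squared distances between rows of a (n x 3) and b (m x 3).
cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
}
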