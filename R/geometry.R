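# Internal rigid-geometry primitives shared by the backbone builder, the
# threading engine and the fibril-structure classifiers.  All coordinates are
# plain numeric matrices with one row per atom and columns x, y, z (angstrom).

#' @keywords internal
vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' @keywords internal
vnorm <- function(a) sqrt(sum(a * a))

#' @keywords internal
vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  a / n
}

#' Place an atom from internal coordinates (natural extension reference frame)
#'
#' Given three previously placed atoms \code{a}, \code{b}, \code{c} (each an
#' xyz vector), returns the position of a new atom \code{d} bonded to
#' \code{c} with bond length \code{bond}, bond angle \code{angle} (b-c-d,
#' degrees) and torsion \code{torsion} (a-b-c-d, degrees).
#'
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)                 # bc, m, n form a right-handed frame
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

#' Torsion angle defined by four points, in degrees in (-180, 180]
#' @keywords internal
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(vcross(n1, n2) * vunit(b2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Bond angle at p2 (p1-p2-p3), degrees
#' @keywords internal
bond_angle <- function(p1, p2, p3) {
  u <- vunit(p1 - p2)
  v <- vunit(p3 - p2)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

#' Rotation matrix for a rotation of \code{theta} degrees about unit axis
#' @keywords internal
rotation_about_axis <- function(axis, theta) {
  u <- vunit(axis)
  th <- theta * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  matrix(c(
    ct + ux^2 * (1 - ct),       ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),       uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3L, byrow = TRUE)
}

#' Apply a rigid transform (3x3 rotation R, length-3 translation t) to an
#' n x 3 coordinate matrix.
#' @keywords internal
apply_rigid <- function(xyz, R, t = c(0, 0, 0)) {
  sweep(xyz %*% t(R), 2L, -t)
}

#' Random rigid transform drawn from a seeded RNG state (rotation uniform on
#' SO(3) via normalized quaternion, translation uniform in a cube).
#' @keywords internal
random_rigid <- function(max_translation = 20) {
  q <- stats::rnorm(4L)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
  list(R = R, t = stats::runif(3L, -max_translation, max_translation))
}

#' Least-squares superposition RMSD (Kabsch) between two n x 3 matrices
#' @keywords internal
superpose_rmsd <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  ac <- sweep(a, 2L, colMeans(a))
  bc <- sweep(b, 2L, colMeans(b))
  s <- svd(t(ac) %*% bc)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  diff <- bc %*% R - ac
  sqrt(sum(diff^2) / nrow(a))
}
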