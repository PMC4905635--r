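# Internal 3D geometry primitives shared by the structure builders.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed dihedral angle (degrees) defined by four points
#'
#' Torsion about the `b`--`c` bond, IUPAC sign convention.
#'
#' @param a,b,c,d numeric xyz vectors (Angstrom).
#' @return angle in degrees in (-180, 180].
#' @keywords internal
dihedral_angle <- function(a, b, c, d) {
  b0 <- a - b
  b1 <- unit(c - b)
  b2 <- d - c
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  y <- sum(cross3(b1, v) * w)
  atan2(y, x) * 180 / pi
}

angle_deg <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Returns the position of atom D bonded to `c` with bond length `bond`,
#' valence angle `angle` (D-c-b) and torsion `torsion` (a-b-c-D), degrees.
#'
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cbind(bc, cross3(n, bc), n)
  as.numeric(m %*% d2 + c)
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' paired coordinate sets, and reports the post-fit RMSD.
#'
#' @param mobile n x 3 matrix of coordinates to move.
#' @param reference n x 3 matrix of target coordinates, paired row-by-row.
#' @return list with `rotation` (3 x 3, det = +1), `translation` (length 3),
#'   `rmsd` (Angstrom). The transform maps `mobile` onto `reference` as
#'   `mobile %*% t(rotation) + translation` (rowwise).
#' @export
#' @examples
#' x <- matrix(rnorm(12), 4, 3)
#' fit <- superpose(x, x)
#' stopifnot(fit$rmsd < 1e-12)
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)))
    stop("mobile and reference selections differ in length")
  if (nrow(mobile) < 3)
    stop("superposition needs at least 3 paired atoms")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  x <- sweep(mobile, 2, cm)
  y <- sweep(reference, 2, cr)
  h <- t(x) %*% y
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  moved <- x %*% t(rot)
  rmsd <- sqrt(mean(rowSums((moved - y)^2)))
  list(rotation = rot,
       translation = as.numeric(cr - (rot %*% cm)),
       rmsd = rmsd)
}

#' Apply a rigid transform to a coordinate matrix
#' @keywords internal
apply_transform <- function(xyz, rotation, translation) {
  sweep(as.matrix(xyz) %*% t(rotation), 2, -translation)
}

#' Rotation matrix about an arbitrary axis
#'
#' @param axis length-3 axis (normalized internally).
#' @param angle rotation angle in degrees.
#' @return 3 x 3 proper rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- unit(axis)
  th <- angle * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * ux + (1 - ct) * (u %o% u)
}
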