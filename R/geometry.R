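## Core 3D geometry: dihedrals, internal-coordinate atom placement (NeRF),
## and Kabsch least-squares superposition. All coordinates in Angstrom,
## all angles in degrees unless noted.

#' Ideal backbone geometry constants
#'
#' Bond lengths (Angstrom) and bond angles (degrees) used when rebuilding
#' idealized backbones from torsions. Values are the standard
#' Engh-Huber-style ideal internal coordinates for the peptide unit.
#'
#' @return Named list with elements `b_n_ca`, `b_ca_c`, `b_c_n`, `b_c_o`,
#'   `b_ca_cb`, `a_n_ca_c`, `a_ca_c_n`, `a_c_n_ca`, `a_ca_c_o`, `a_n_ca_cb`,
#'   `t_c_n_ca_cb` (the improper torsion that fixes L-chirality of CB).
#' @export
ideal_geometry <- function() {
  list(
    b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
    b_c_o = 1.231, b_ca_cb = 1.521,
    a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
    a_ca_c_o = 120.8, a_n_ca_cb = 110.5,
    t_c_n_ca_cb = -122.6
  )
}

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Dihedral angle of four points
#'
#' Signed torsion angle a-b-c-d by the IUPAC convention, in degrees in
#' (-180, 180]. Computed with the atan2 formulation, which is numerically
#' stable near 0 and 180 degrees.
#'
#' @param a,b,c,d Numeric 3-vectors (Angstrom).
#' @return Angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- .rad2deg(atan2(-y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Natural-extension-of-reference-frame placement: given three previously
#' placed atoms a-b-c, returns the position of atom d at bond length
#' `bond` from c, bond angle `angle` at c (between b-c and c-d), and
#' torsion `torsion` about b-c measured a-b-c-d.
#'
#' @param a,b,c Numeric 3-vectors, the reference frame atoms.
#' @param bond Bond length c-d in Angstrom.
#' @param angle Bond angle b-c-d in degrees.
#' @param torsion Dihedral a-b-c-d in degrees.
#' @return Numeric 3-vector, the position of d.
#' @export
nerf_place <- function(a, b, c, bond, angle, torsion) {
  th <- .deg2rad(angle)
  ph <- .deg2rad(torsion)
  d_local <- c(-bond * cos(th),
               bond * sin(th) * cos(ph),
               bond * sin(th) * sin(ph))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- .cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  rot <- cbind(bc, m, n)
  c(rot %*% d_local) + c
}

#' Kabsch superposition of two point sets
#'
#' Least-squares rigid-body superposition of `mobile` onto `fixed` using the
#' SVD (Kabsch) algorithm, with the determinant correction that guarantees a
#' proper rotation (no reflection).
#'
#' @param mobile,fixed Numeric n x 3 matrices of paired coordinates, n >= 3.
#' @return List with `rotation` (3 x 3, det +1), `translation` (3-vector),
#'   `rmsd` (Angstrom). The transform maps mobile points as
#'   `x %*% t(rotation) + translation`.
#' @examples
#' p <- matrix(rnorm(30), 10, 3)
#' fit <- kabsch_superpose(p, p)
#' fit$rmsd  # 0
#' @export
kabsch_superpose <- function(mobile, fixed) {
  mobile <- as.matrix(mobile); fixed <- as.matrix(fixed)
  if (nrow(mobile) != nrow(fixed) || ncol(mobile) != 3 || ncol(fixed) != 3)
    stop("mobile and fixed must be equal-length n x 3 matrices")
  if (nrow(mobile) < 3)
    stop("at least 3 points are required for superposition")
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  x <- sweep(mobile, 2, cm); y <- sweep(fixed, 2, cf)
  # collinearity check: rank of the centered set must be >= 2
  if (sum(svd(x)$d > 1e-8) < 2 || sum(svd(y)$d > 1e-8) < 2)
    stop("degenerate (collinear) point set: superposition is underdetermined")
  s <- svd(t(x) %*% y)
  d <- sign(det(s$v %*% t(s$u)))
  dd <- diag(c(1, 1, d))
  rot <- s$v %*% dd %*% t(s$u)
  moved <- x %*% t(rot)
  rmsd <- sqrt(mean(rowSums((moved - y)^2)))
  list(rotation = rot, translation = cf - c(rot %*% cm), rmsd = rmsd)
}

#' Apply a rigid-body transform to coordinates
#'
#' @param xyz n x 3 matrix.
#' @param fit List with `rotation` and `translation` as returned by
#'   [kabsch_superpose()].
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, fit) {
  sweep(as.matrix(xyz) %*% t(fit$rotation), 2, fit$translation, "+")
}

#' Backbone-atom RMSD after optimal superposition
#'
#' @param a,b n x 3 coordinate matrices.
#' @return RMSD in Angstrom after Kabsch superposition.
#' @export
superposed_rmsd <- function(a, b) kabsch_superpose(a, b)$rmsd

## Rotation of points about an arbitrary axis (Rodrigues), used by the
## CCD closure. `axis_point`/`axis_dir` define the axis, theta in radians.
.rotate_about_axis <- function(xyz, axis_point, axis_dir, theta) {
  u <- axis_dir / sqrt(sum(axis_dir^2))
  k <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  r <- diag(3) + sin(theta) * k + (1 - cos(theta)) * (k %*% k)
  m <- as.matrix(xyz)
  p <- matrix(axis_point, nrow(m), 3, byrow = TRUE)
  (m - p) %*% t(r) + p
}

.wrap_angle <- function(x) {
  x <- (x + 180) %% 360 - 180
  x[!is.na(x) & x == -180] <- 180
  x
}
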