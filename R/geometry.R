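# Small vector-geometry kernel shared by the structure builder and the
# metrics: dihedrals, axis rotations, and internal-coordinate atom placement.

#' Dihedral angle of four points
#'
#' Computes the torsion angle defined by four points using the
#' atan2 formulation, which is numerically stable near 0 and 180 degrees.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (coordinates in Angstrom).
#' @return Angle in degrees in (-180, 180].
#' @keywords internal
dihedral_angle <- function(p1, p2, p3, p4) {
  # IUPAC sign convention: looking down p2 -> p3, clockwise is positive
  b0 <- p1 - p2
  b1 <- p3 - p2
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- p4 - p3
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  y <- sum(cross3(b1, v) * w)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix about an arbitrary axis (Rodrigues' formula)
#'
#' @param axis Numeric 3-vector, need not be normalized.
#' @param theta Angle in degrees.
#' @return 3x3 rotation matrix.
#' @keywords internal
rotation_about_axis <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  th <- theta * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy,
                uz, 0, -ux,
                -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Given three already-placed atoms a, b, c, places atom d at bond length
#' `r` from c, bond angle `theta` (b-c-d) and dihedral `chi` (a-b-c-d).
#'
#' @param a,b,c Numeric 3-vectors of reference atoms.
#' @param r Bond length in Angstrom.
#' @param theta Bond angle in degrees.
#' @param chi Dihedral angle in degrees.
#' @return Numeric 3-vector with the new position.
#' @keywords internal
place_atom <- function(a, b, c, r, theta, chi) {
  th <- theta * pi / 180
  ph <- chi * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- cross3(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- c(-r * cos(th), r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# circular difference in degrees on a given period (360 for ordinary
# dihedrals, 180 for symmetric terminal groups)
circ_diff <- function(a, b, period = 360) {
  d <- abs((a - b) %% period)
  pmin(d, period - d)
}
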