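# Vector geometry used by every classifier. All coordinates are in Angstroms,
# all angles are returned in degrees. Functions accept either single 3-vectors
# or n x 3 matrices (row-wise, vectorised).

.as_mat3 <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    x
  } else {
    stopifnot(length(x) == 3)
    matrix(x, ncol = 3)
  }
}

.rad2deg <- function(x) x * 180 / pi

.row_norm <- function(m) sqrt(rowSums(m * m))

.row_unit <- function(m) {
  n <- .row_norm(m)
  if (any(n < 1e-12)) stop("degenerate geometry: zero-length vector")
  m / n
}

.row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Euclidean distance between points
#'
#' @param a,b 3-vectors or n x 3 matrices of coordinates (Angstroms).
#' @return Distance(s) in Angstroms.
#' @export
#' @examples
#' atom_distance(c(0, 0, 0), c(3, 4, 0)) # 5
atom_distance <- function(a, b) {
  a <- .as_mat3(a); b <- .as_mat3(b)
  .row_norm(a - b)
}

#' Bond angle at a vertex
#'
#' Angle a-b-c measured at `b`, in degrees.
#'
#' @param a,b,c 3-vectors or n x 3 matrices (Angstroms).
#' @return Angle(s) in degrees, in [0, 180].
#' @export
bond_angle <- function(a, b, c) {
  a <- .as_mat3(a); b <- .as_mat3(b); c <- .as_mat3(c)
  u <- .row_unit(a - b)
  v <- .row_unit(c - b)
  .rad2deg(acos(pmin(1, pmax(-1, rowSums(u * v)))))
}

#' Torsion angle magnitude
#'
#' Absolute dihedral a-b-c-d about the b-c axis, in degrees in [0, 180].
#' Every threshold applied downstream is a one-sided magnitude, so the sign
#' of the torsion is deliberately dropped.
#'
#' @param a,b,c,d 3-vectors or n x 3 matrices (Angstroms).
#' @return Magnitude(s) of the torsion in degrees.
#' @export
dihedral_angle <- function(a, b, c, d) {
  a <- .as_mat3(a); b <- .as_mat3(b); c <- .as_mat3(c); d <- .as_mat3(d)
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- .row_cross(b1, b2)
  n2 <- .row_cross(b2, b3)
  if (any(.row_norm(n1) < 1e-9) || any(.row_norm(n2) < 1e-9))
    stop("degenerate geometry: collinear atoms in dihedral")
  m1 <- .row_cross(n1, .row_unit(b2))
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  abs(.rad2deg(atan2(y, x)))
}

# Signed torsion in (-180, 180]; used by the peptide builder where chirality
# and direction matter.
.dihedral_signed <- function(a, b, c, d) {
  a <- .as_mat3(a); b <- .as_mat3(b); c <- .as_mat3(c); d <- .as_mat3(d)
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- .row_cross(b1, b2)
  n2 <- .row_cross(b2, b3)
  m1 <- .row_cross(n1, .row_unit(b2))
  -.rad2deg(atan2(rowSums(m1 * n2), rowSums(n1 * n2)))
}

#' Elevation of a point above a plane
#'
#' Elevation angle of point `p` relative to the plane through three atoms,
#' measured from a reference origin in the plane (by default the third plane
#' atom, which for a carbonyl plane Ca-C-O is the oxygen). 0 degrees means
#' `p` lies in the plane; 90 degrees means `p` sits on the plane normal
#' through the origin.
#'
#' @param p Query point (3-vector or n x 3 matrix).
#' @param a,b,c The three non-collinear atoms defining the plane.
#' @param origin In-plane reference point the elevation is measured at;
#'   defaults to `c`.
#' @return Elevation angle(s) in degrees, in [0, 90].
#' @export
elevation_angle <- function(p, a, b, c, origin = c) {
  p <- .as_mat3(p); a <- .as_mat3(a); b <- .as_mat3(b); c <- .as_mat3(c)
  origin <- .as_mat3(origin)
  n <- .row_cross(b - a, c - a)
  if (any(.row_norm(n) < 1e-9)) stop("degenerate geometry: collinear plane atoms")
  n <- .row_unit(n)
  v <- .row_unit(p - origin)
  alpha <- .rad2deg(acos(pmin(1, pmax(-1, rowSums(v * n)))))
  abs(90 - alpha)
}

# Place atom D given atoms A-B-C, the bond length |C-D|, the angle B-C-D
# (degrees) and the signed torsion A-B-C-D (degrees). Standard internal-to-
# Cartesian (NeRF) step used by the peptide builder.
.place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc * bc))
  ab <- b - a
  n0 <- c(ab[2] * bc[3] - ab[3] * bc[2],
          ab[3] * bc[1] - ab[1] * bc[3],
          ab[1] * bc[2] - ab[2] * bc[1])
  nn <- sqrt(sum(n0 * n0))
  if (nn < 1e-10) stop("degenerate geometry: collinear reference atoms")
  n0 <- n0 / nn
  m0 <- c(n0[2] * bc[3] - n0[3] * bc[2],
          n0[3] * bc[1] - n0[1] * bc[3],
          n0[1] * bc[2] - n0[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m0 + d2[3] * n0
}
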