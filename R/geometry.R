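# Small vector-geometry kernel: dihedrals, internal-coordinate atom
# placement (NeRF), and Kabsch superposition.  Angles are radians
# throughout; coordinates are Angstrom.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) internal_error("degenerate zero-length vector")
  a / n
}

#' Dihedral angle of four points
#'
#' Signed torsion angle A-B-C-D in radians, in (-pi, pi], following the
#' IUPAC convention (looking from B to C, clockwise positive).
#'
#' @param a,b,c,d Numeric 3-vectors (Angstrom).
#' @return Angle in radians.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b0 <- a - b
  b1 <- vunit(c - b)
  b2 <- d - c
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  y <- sum(vcross(b1, v) * w)
  ang <- atan2(y, x)
  if (ang <= -pi) ang <- ang + 2 * pi
  ang
}

# Bond angle at b (radians)
bond_angle <- function(a, b, c) {
  u <- vunit(a - b)
  v <- vunit(c - b)
  acos(max(-1, min(1, sum(u * v))))
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Given three placed atoms `a`, `b`, `c`, returns the position `d` such
#' that |c-d| = `bond`, the angle b-c-d equals `angle` and the dihedral
#' a-b-c-d equals `dihedral`.
#'
#' @param a,b,c Numeric 3-vectors of already-placed atoms.
#' @param bond Bond length c-d (Angstrom).
#' @param angle Bond angle b-c-d (radians).
#' @param dihedral Torsion a-b-c-d (radians).
#' @return Numeric 3-vector.
#' @export
nerf_place <- function(a, b, c, bond, angle, dihedral) {
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- bond * c(-cos(angle),
                 sin(angle) * cos(dihedral),
                 sin(angle) * sin(dihedral))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Optimal rotation between two coordinate sets (Kabsch)
#'
#' Returns the proper rotation matrix `R` minimising the RMSD of
#' `x %*% R` onto `y` after both sets are centred; reflections are
#' excluded by the usual determinant correction.
#'
#' @param x,y n x 3 matrices of paired coordinates (already centred).
#' @param w Optional non-negative per-point weights.
#' @return 3 x 3 rotation matrix.
#' @export
kabsch_rotation <- function(x, y, w = NULL) {
  if (!is.null(w)) {
    x <- x * sqrt(w)
    y <- y * sqrt(w)
  }
  h <- crossprod(x, y)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

# Superpose x onto y (both n x 3); returns transformed x and the RMSD.
superpose_onto <- function(x, y, w = NULL) {
  if (is.null(w)) w <- rep(1, nrow(x))
  w <- w / sum(w)
  cx <- colSums(x * w)
  cy <- colSums(y * w)
  xc <- sweep(x, 2, cx)
  yc <- sweep(y, 2, cy)
  r <- kabsch_rotation(xc, yc, w)
  xt <- xc %*% r
  rmsd <- sqrt(sum(w * rowSums((xt - yc)^2)))
  list(coords = sweep(xt, 2, cy, "+"), rmsd = rmsd)
}

# RMSD of x onto y after optimal superposition (unweighted).
superposed_rmsd <- function(x, y) {
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  r <- kabsch_rotation(xc, yc)
  sqrt(mean(rowSums((xc %*% r - yc)^2)))
}

# Apply a rigid transform (3x3 rotation + translation 3-vector) to n x 3.
apply_rigid <- function(coords, rot, trans) {
  sweep(coords %*% t(rot), 2, trans, "+")
}

# Rotation matrix from axis (unit 3-vector) and angle.
axis_angle_matrix <- function(axis, theta) {
  u <- vunit(axis)
  ct <- cos(theta); st <- sin(theta)
  ux <- matrix(c(0, -u[3], u[2],
                 u[3], 0, -u[1],
                 -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * ux + (1 - ct) * (u %o% u)
}
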