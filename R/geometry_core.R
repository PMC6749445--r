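# Vector-geometry primitives shared by every metric. All angles in degrees,
# torsions wrapped to (-180, 180].

DEG <- 180 / pi

#' Euclidean norm of a 3-vector
#' @noRd
vnorm <- function(v) sqrt(sum(v * v))

#' @noRd
vunit <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

#' @noRd
vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Wrap an angle in degrees to (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return wrapped angles.
#' @export
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Bond angle at a vertex
#'
#' Inner angle at `p2` between the rays towards `p1` and `p3`.
#'
#' @param p1,p2,p3 numeric 3-vectors (angstrom).
#' @return angle in degrees, in \[0, 180\].
#' @export
angle3 <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  nu <- vnorm(u)
  nv <- vnorm(v)
  if (nu == 0 || nv == 0) {
    stop("coincident points: angle undefined", call. = FALSE)
  }
  # atan2 form is numerically stable near 0 and 180 degrees
  atan2(vnorm(vcross(u, v)), sum(u * v)) * DEG
}

#' Signed dihedral (torsion) angle
#'
#' IUPAC convention: looking from `p2` towards `p3`, a clockwise rotation of the
#' far bond relative to the near bond is positive. Eclipsed (cis) is 0 degrees,
#' anti (trans) is 180 degrees.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (angstrom).
#' @return signed angle in degrees, in (-180, 180\].
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  lb2 <- vnorm(b2)
  if (lb2 == 0) stop("p2 and p3 coincide: dihedral undefined", call. = FALSE)
  # collinearity guard for either bounding triple
  if (vnorm(n1) < 1e-10 * vnorm(b1) * lb2 ||
      vnorm(n2) < 1e-10 * lb2 * vnorm(b3)) {
    stop("collinear triple: dihedral undefined", call. = FALSE)
  }
  x <- sum(n1 * n2)
  y <- sum(vcross(n1, n2) * b2) / lb2
  wrap180(atan2(y, x) * DEG)
}

#' Least-squares plane through a point cloud
#'
#' Minimizes the sum of squared perpendicular distances (total least squares,
#' via SVD of the centred coordinates).
#'
#' @param points numeric matrix, n x 3, n >= 3, not all collinear.
#' @return object of class `Plane`: list with `normal` (unit 3-vector),
#'   `centroid` (3-vector) and `rmsd` (angstrom, root-mean-square out-of-plane
#'   deviation of the fitted points).
#' @export
fit_plane <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("need at least 3 points to fit a plane", call. = FALSE)
  ctr <- colMeans(points)
  x <- sweep(points, 2, ctr)
  sv <- svd(x)
  # collinear cloud: second singular value vanishes relative to the first
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-300)) {
    stop("points are collinear: plane undefined", call. = FALSE)
  }
  normal <- sv$v[, 3]
  d <- as.vector(x %*% normal)
  structure(
    list(normal = normal / vnorm(normal), centroid = ctr,
         rmsd = sqrt(mean(d^2))),
    class = "Plane"
  )
}

#' Rotation matrix for a rotation about an arbitrary axis
#'
#' @param axis numeric 3-vector, need not be unit length.
#' @param theta_deg rotation angle, degrees (right-hand rule).
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, theta_deg) {
  u <- vunit(axis)
  th <- theta_deg / DEG
  ct <- cos(th)
  st <- sin(th)
  ux <- matrix(c(0, -u[3], u[2],
                 u[3], 0, -u[1],
                 -u[2], u[1], 0), 3, 3, byrow = TRUE)
  ct * diag(3) + st * ux + (1 - ct) * (u %o% u)
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Returns the position `d` with `|d - c| = bond`, inner angle `angle3(b, c, d)
#' = angle_deg` and torsion `dihedral(a, b, c, d) = torsion_deg`.
#'
#' @param a,b,c reference positions (3-vectors).
#' @param bond bond length, angstrom.
#' @param angle_deg bond angle at `c`, degrees.
#' @param torsion_deg torsion about `b`-`c`, degrees.
#' @return numeric 3-vector.
#' @export
place_internal <- function(a, b, c, bond, angle_deg, torsion_deg) {
  th <- angle_deg / DEG
  ph <- torsion_deg / DEG
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d_local <- c(-bond * cos(th),
               bond * sin(th) * cos(ph),
               bond * sin(th) * sin(ph))
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

#' Random rigid-body transform (rotation + translation)
#' @noRd
random_rigid_transform <- function(max_shift = 20) {
  ax <- stats::rnorm(3)
  R <- rotation_about_axis(ax, stats::runif(1, 0, 360))
  t <- stats::runif(3, -max_shift, max_shift)
  list(R = R, t = t)
}

#' Apply a rigid transform to an n x 3 coordinate matrix
#' @noRd
apply_rigid <- function(xyz, tr) {
  sweep(as.matrix(xyz) %*% t(tr$R), 2, tr$t, `+`)
}
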