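# Independent oracles and small text fixtures shared across the suite.

# Rotation-matrix dihedral oracle: rotate the frame so b2 lies on +z, then
# read the signed angle between the xy-projections of the outer bonds.
# Independent of the atan2/cross-product path used by dihedral().
oracle_dihedral <- function(p1, p2, p3, p4) {
  b2 <- p3 - p2
  u <- b2 / sqrt(sum(b2^2))
  z <- c(0, 0, 1)
  v <- c(u[2] * z[3] - u[3] * z[2],
         u[3] * z[1] - u[1] * z[3],
         u[1] * z[2] - u[2] * z[1])
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    R <- if (u[3] > 0) diag(3) else diag(c(1, -1, -1))
  } else {
    vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                 byrow = TRUE)
    cth <- sum(u * z)
    R <- diag(3) + vx + vx %*% vx / (1 + cth)
  }
  a <- as.vector(R %*% (p1 - p2))
  b <- as.vector(R %*% (p4 - p3))
  th1 <- atan2(a[2], a[1])
  th2 <- atan2(b[2], b[1])
  # looking from p2 towards p3 the axis points away from the viewer, so a
  # clockwise (positive, IUPAC) rotation is counterclockwise in atan2 terms
  d <- (th2 - th1) * 180 / pi
  d <- (d + 180) %% 360 - 180
  if (d == -180) d <- 180
  d
}

# PCA plane oracle: smallest-eigenvector plane from the covariance matrix
# (eigen path, independent of the SVD path in fit_plane()).
oracle_plane_normal <- function(points) {
  x <- sweep(points, 2, colMeans(points))
  eigen(crossprod(x), symmetric = TRUE)$vectors[, 3]
}

random_points <- function(n, spread = 5) {
  matrix(stats::rnorm(n * 3, sd = spread), ncol = 3)
}

rigid_transform_model <- function(model, R, t) {
  a <- model$atoms
  xyz <- sweep(as.matrix(a[, c("x", "y", "z")]) %*% t(R), 2, t, `+`)
  a[, c("x", "y", "z")] <- xyz
  structure_model(a, entry_id = model$entry_id)
}

random_rotation <- function() {
  ax <- stats::rnorm(3)
  rotation_about_axis(ax, stats::runif(1, 0, 360))
}

# Minimal fixed-column PDB fixture: three residues (ALA, GLY, HOH), two
# ANISOU records, written through the package-independent text below.
tripeptide_pdb_lines <- function() {
  c("HEADER    TEST FIXTURE                                 SYNF",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 10.00           C",
    "ANISOU    2  CA  ALA A   1     1266   1266   1266      0      0      0       C",
    "ATOM      3  C   ALA A   1       2.004   1.420   0.000  1.00 10.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00 10.00           O",
    "ATOM      5  CB  ALA A   1       2.000  -0.750  -1.250  1.00 10.00           C",
    "ATOM      6  N   GLY A   2       3.330   1.540   0.000  1.00 12.00           N",
    "ANISOU    6  N   GLY A   2     1519   1519   1519      0      0      0       N",
    "ATOM      7  CA  GLY A   2       3.990   2.840   0.000  1.00 12.00           C",
    "ATOM      8  C   GLY A   2       5.500   2.700   0.000  1.00 12.00           C",
    "ATOM      9  O   GLY A   2       6.100   1.620   0.000  1.00 12.00           O",
    "HETATM   10  O   HOH A 101       8.000   8.000   8.000  1.00 25.00           O",
    "END")
}

write_tripeptide_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(tripeptide_pdb_lines(), path)
  path
}

altloc_pdb_lines <- function() {
  c("ATOM      1  N   SER A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  SER A   1       1.458   0.000   0.000  1.00 10.00           C",
    "ATOM      3  C   SER A   1       2.004   1.420   0.000  1.00 10.00           C",
    "ATOM      4  O   SER A   1       1.251   2.390   0.000  1.00 10.00           O",
    "ATOM      5  CB ASER A   1       2.000  -0.800  -1.200  0.50 10.00           C",
    "ATOM      6  CB BSER A   1       2.000  -0.900  -1.100  0.50 11.00           C",
    "ATOM      7  OG ASER A   1       3.400  -0.800  -1.200  0.30 10.00           O",
    "ATOM      8  OG BSER A   1       3.400  -0.900  -1.100  0.70 11.00           O",
    "END")
}

expect_angle_equal <- function(x, y, tol) {
  d <- abs((x - y + 180) %% 360 - 180)
  expect_lt(d, tol)
}
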