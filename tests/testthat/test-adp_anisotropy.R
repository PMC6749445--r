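mk_atom <- function(u, b = NA_real_, class = "ALA") {
  data.frame(record = "ATOM", serial = 1L, atom = "CA", altloc = "",
             resname = class, chain = "A", resno = 1L, ins = "",
             x = 0, y = 0, z = 0, occ = 1,
             b = if (is.na(b)) (8 * pi^2 / 3) * sum(diag(u)) else b,
             element = "C",
             u11 = u[1, 1], u22 = u[2, 2], u33 = u[3, 3],
             u12 = u[1, 2], u13 = u[1, 3], u23 = u[2, 3],
             stringsAsFactors = FALSE)
}

test_that("atom_anisotropy computes the min/max eigenvalue ratio", {
  iso <- atom_anisotropy(mk_atom(0.01 * diag(3)))
  expect_equal(iso$anisotropy, 1, tolerance = 1e-12)
  t <- atom_anisotropy(mk_atom(diag(c(0.04, 0.02, 0.01))))
  expect_equal(t$anisotropy, 0.25, tolerance = 1e-12)
  expect_equal(t$eigenvalues, c(0.04, 0.02, 0.01), tolerance = 1e-12)
  expect_equal(t$b_eq, (8 * pi^2 / 3) * 0.07, tolerance = 1e-12)
  expect_error(atom_anisotropy(mk_atom(diag(3) * NA_real_)), "no uij")
})

test_that("anisotropy is rotation invariant and trace is conserved", {
  set.seed(19)
  U0 <- diag(c(0.04, 0.02, 0.01))
  for (k in 1:200) {
    R <- random_rotation()
    U <- R %*% U0 %*% t(R)
    t <- atom_anisotropy(mk_atom(U))
    expect_lt(abs(t$anisotropy - 0.25), 1e-9)
    expect_lt(abs(sum(t$eigenvalues) - sum(diag(U))), 1e-12)
  }
})

test_that("non-positive-definite tensors are flagged and excluded from stats", {
  bad <- atom_anisotropy(mk_atom(diag(c(0.04, 0.02, -0.01))))
  expect_false(bad$valid)
  expect_true(is.na(bad$anisotropy))
  atoms <- rbind(mk_atom(0.01 * diag(3)), mk_atom(diag(c(0.04, 0.02, -0.01))))
  atoms$resno <- 1:2
  g <- group_anisotropy(structure_model(atoms))
  expect_equal(g$n, 1)
  expect_equal(g$n_invalid, 1)
  expect_equal(g$mean_anisotropy, 1)
})

test_that("group statistics: mean, population sd, group partition", {
  iso <- do.call(rbind, lapply(1:10, function(i) {
    a <- mk_atom(0.02 * diag(3)); a$resno <- i; a
  }))
  g <- group_anisotropy(structure_model(iso))
  expect_equal(g$mean_anisotropy, 1)
  expect_equal(g$sd_anisotropy, 0)
  expect_equal(g$n, 10)

  mixed <- do.call(rbind, lapply(1:10, function(i) {
    u <- if (i <= 5) diag(c(0.05, 0.02, 0.01)) else diag(c(0.01, 0.008, 0.006))
    a <- mk_atom(u); a$resno <- i; a
  }))
  gm <- group_anisotropy(structure_model(mixed))
  expect_equal(gm$mean_anisotropy, 0.4, tolerance = 1e-12)
  expect_equal(gm$sd_anisotropy, 0.2, tolerance = 1e-12)

  # separate groups: one polymer, one solvent, no ligand row at all
  two <- rbind(mk_atom(0.01 * diag(3), class = "ALA"),
               mk_atom(0.02 * diag(3), class = "HOH"))
  two$resno <- 1:2
  g2 <- group_anisotropy(structure_model(two))
  expect_setequal(g2$group, c("protein", "solvent"))

  empty <- group_anisotropy(structure_model(
    build_peptide("ALA")))   # no uij anywhere
  expect_equal(nrow(empty), 0)
})

test_that("hydrogen exclusion and inclusion are both available", {
  hx <- build_element("helix", n = 4)
  m <- attach_adps(place_hydrogens(hx$model), 0.5, c(0, 0, 1), 8)
  g_excl <- group_anisotropy(m, exclude_hydrogen = TRUE)
  g_incl <- group_anisotropy(m, exclude_hydrogen = FALSE)
  expect_lt(g_excl$n, g_incl$n)
  expect_equal(g_excl$mean_anisotropy, 0.5, tolerance = 1e-9)
})

test_that("group B factors average b_iso per class", {
  atoms <- rbind(mk_atom(0.01 * diag(3), b = 10),
                 mk_atom(0.01 * diag(3), b = 20))
  atoms$resno <- 1:2
  g <- group_b_factor(structure_model(atoms))
  expect_equal(g$mean_b, 15)
  expect_equal(g$n, 2)
})

test_that("synthetic ADP recovery is exact over the anisotropy grid", {
  base <- structure_model(build_peptide(c("ALA", "ALA")))
  for (a in seq(0.1, 1, by = 0.1)) {
    m <- attach_adps(base, a, axis = c(1, 1, 0), b_eq = 12)
    t <- atom_anisotropy(m$atoms[1, ])
    expect_lt(abs(t$anisotropy - a), 1e-9)
    expect_lt(abs(t$b_eq - 12), 1e-9)
  }
  expect_error(attach_adps(base, 0, c(0, 0, 1), 10), "anisotropy")
  expect_error(attach_adps(base, 0.5, c(0, 0, 0), 10), "axis")
  expect_error(attach_adps(base, 0.5, c(0, 0, 1), -1), "b_eq")
})

test_that("axis export aligns with the constructed elongation and skips degenerate atoms", {
  hx <- build_element("helix", n = 6)
  m <- attach_adps(hx$model, 0.25, axis = c(0, 0, 1), b_eq = 10)
  lines <- export_axes(m, scale = 10)
  axes <- attr(lines, "axes")
  expect_gt(nrow(axes), 0)
  expect_true(all(abs(abs(axes$dz) - 1) < 1e-9))
  expect_true(any(grepl("CYLINDER", lines)))

  iso <- attach_adps(hx$model, 1, axis = c(0, 0, 1), b_eq = 10)
  li <- export_axes(iso, scale = 10)
  expect_null(attr(li, "axes"))
  expect_gt(attr(li, "n_degenerate"), 0)
})
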