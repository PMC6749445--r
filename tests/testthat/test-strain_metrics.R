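test_that("ideal residues measure zero on every bending metric", {
  fns <- list(ARG = arg_twist, PHE = phe_bend, TRP = trp_bend, TYR = tyr_bend)
  for (ty in names(fns)) {
    b <- build_residue(ty)
    m <- fns[[ty]](b$residue)
    expect_lt(abs(m$value), 0.01)
    expect_equal(m$reference, 0)
  }
})

test_that("applied distortions are recovered exactly, with sign", {
  cases <- list(
    list("ARG", "guanidinium_twist", arg_twist, c(1, -2, 5, -10, 20)),
    list("PHE", "cb_bend", phe_bend, c(1, 2, 5, 10, 20)),
    list("TRP", "cb_bend", trp_bend, c(1, -2, 5, -10, 20)),
    list("TYR", "cb_bend", tyr_bend, c(1, 2, 5, 10, 20))
  )
  for (cs in cases) {
    for (delta in cs[[4]]) {
      b <- build_residue(cs[[1]], distortion_spec(cs[[2]], delta))
      m <- cs[[3]](b$residue)
      expect_equal(m$value, b$ground_truth$value, tolerance = 1e-6)
      expect_lt(abs(m$value - if (cs[[1]] %in% c("PHE", "TYR")) abs(delta)
                    else delta), 0.05)
    }
  }
})

test_that("swapped eta-nitrogen naming is normalized back towards zero", {
  b <- build_residue("ARG", distortion_spec("guanidinium_twist", 4))
  a <- b$model$atoms
  i1 <- which(a$atom == "NH1"); i2 <- which(a$atom == "NH2")
  a$atom[i1] <- "NH2"; a$atom[i2] <- "NH1"
  res <- residue_views(structure_model(a))[[1]]
  m <- arg_twist(res)
  expect_lt(abs(abs(m$value) - 4), 0.05)
  expect_equal(m$note, "nh1_nh2_normalized")
  # a planar guanidinium is 0 or 180, never intermediate; both report ~0
  b0 <- build_residue("ARG")
  a0 <- b0$model$atoms
  j1 <- which(a0$atom == "NH1"); j2 <- which(a0$atom == "NH2")
  a0$atom[j1] <- "NH2"; a0$atom[j2] <- "NH1"
  expect_lt(abs(arg_twist(residue_views(structure_model(a0))[[1]])$value), 0.01)
})

test_that("missing atoms skip the measurement with a logged reason", {
  b <- build_residue("ARG")
  a <- b$model$atoms[b$model$atoms$atom != "NH1", ]
  res <- residue_views(structure_model(a))[[1]]
  expect_warning(m <- arg_twist(res), "missing atom")
  expect_null(m)
})

test_that("omega scan classifies trans and cis and reports signed deviations", {
  om <- rep(180, 4); om[2] <- 170
  v <- residue_views(structure_model(
    build_peptide(rep("ALA", 5), phi = -139, psi = 135, omega = om)))
  ms <- omega_scan(v)
  expect_equal(length(ms), 4)
  devs <- vapply(ms, `[[`, numeric(1), "value")
  expect_equal(devs[2], -10, tolerance = 1e-6)
  expect_lt(max(abs(devs[-2])), 0.01)
  expect_true(all(grepl("^trans", vapply(ms, `[[`, character(1), "note"))))
  # cis-proline-style bond: omega 0 classified cis with reference 0
  omc <- rep(180, 2); omc[1] <- 5
  vc <- residue_views(structure_model(
    build_peptide(c("ALA", "PHE", "ALA"), phi = -80, psi = 150, omega = omc)))
  mc <- omega_scan(vc)
  expect_match(mc[[1]]$note, "^cis")
  expect_equal(mc[[1]]$reference, 0)
  expect_equal(mc[[1]]$value, 5, tolerance = 1e-6)
  expect_match(mc[[2]]$note, "^trans")
})

test_that("chain breaks are skipped in the omega scan", {
  at <- build_peptide(rep("ALA", 5), phi = -139, psi = 135)
  sel <- at$resno > 2
  at[sel, c("x", "y", "z")] <- at[sel, c("x", "y", "z")] + 50
  ms <- omega_scan(residue_views(structure_model(at)))
  expect_equal(length(ms), 3)   # bond 2-3 dropped
})

test_that("all strain metrics are rigid-body invariant", {
  set.seed(41)
  fns <- list(ARG = arg_twist, PHE = phe_bend, TRP = trp_bend, TYR = tyr_bend)
  for (ty in names(fns)) {
    b <- build_residue(ty, distortion_spec(
      if (ty == "ARG") "guanidinium_twist" else "cb_bend", 7))
    v0 <- fns[[ty]](b$residue)$value
    for (k in 1:5) {
      mt <- rigid_transform_model(b$model, random_rotation(), runif(3, -20, 20))
      expect_lt(abs(fns[[ty]](residue_views(mt)[[1]])$value - v0), 1e-6)
    }
  }
  om <- rep(180, 3); om[2] <- 168
  m0 <- structure_model(build_peptide(rep("ALA", 4), omega = om))
  d0 <- vapply(omega_scan(residue_views(m0)), `[[`, numeric(1), "value")
  for (k in 1:5) {
    mt <- rigid_transform_model(m0, random_rotation(), runif(3, -20, 20))
    dt <- vapply(omega_scan(residue_views(mt)), `[[`, numeric(1), "value")
    expect_lt(max(abs(dt - d0)), 1e-6)
  }
})

test_that("flag_outliers counts against the policy thresholds", {
  b <- build_residue("ARG")
  mk <- function(vals) {
    do.call(rbind, lapply(vals, function(v) {
      df <- scan_strain(b$model, metrics = "arg_twist")
      df$value_deg <- v
      df
    }))
  }
  out <- flag_outliers(mk(c(3, 9, 11, 25)), policy = c(arg_twist = 10))
  expect_equal(sum(out$is_outlier), 2)
  expect_equal(attr(out, "summary")$n_outliers, 2)
  zero <- flag_outliers(mk(c(0, 0, 0)))
  expect_equal(sum(zero$is_outlier), 0)
  empty <- flag_outliers(scan_strain(structure_model(
    build_peptide("GLY")), metrics = "arg_twist"))
  expect_equal(nrow(empty), 0)
})

test_that("scan_strain integrates metrics over a mixed model", {
  at1 <- build_peptide(c("ALA", "PHE", "TRP", "ARG", "TYR", "ALA"),
                       phi = -57, psi = -47)
  df <- flag_outliers(scan_strain(structure_model(at1)))
  expect_setequal(unique(df$metric),
                  c("phe_bend", "trp_bend", "arg_twist", "tyr_bend",
                    "omega_dev"))
  # helical context bends the template slightly; nothing should be extreme
  expect_lt(max(abs(df$value_deg)), 6)
  expect_equal(nrow(df[df$metric == "omega_dev", ]), 5)
})
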