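test_that("hydrogen placement adds the topology-forced count", {
  ala <- structure_model(build_peptide("ALA"))
  m <- place_hydrogens(ala)
  added <- m$atoms[m$atoms$provenance == "placed", ]
  # HA, HB1-3, H(N): five atoms
  expect_equal(nrow(added), 5)
  expect_setequal(added$atom, c("HA", "HB1", "HB2", "HB3", "H"))
  expect_true(all(is_hydrogen(added$element)))
  # already protonated + keep_existing: nothing added
  m2 <- place_hydrogens(m, mode = "keep_existing")
  expect_equal(attr(m2, "n_placed"), 0)
  # rebuild_all replaces them
  m3 <- place_hydrogens(m, mode = "rebuild_all")
  expect_equal(attr(m3, "n_placed"), 5)
  expect_equal(sum(is_hydrogen(m3$atoms$element)), 5)
})

test_that("glycine HA pair is mirror-symmetric about the N-CA-C plane", {
  gly <- structure_model(build_peptide("GLY"))
  m <- place_hydrogens(gly)
  a <- m$atoms
  get <- function(nm) unlist(a[a$atom == nm, c("x", "y", "z")], use.names = FALSE)
  h <- a[grepl("^HA", a$atom), ]
  expect_equal(nrow(h), 2)
  pl <- fit_plane(rbind(get("N"), get("CA"), get("C")))
  d1 <- sum((unlist(h[1, c("x", "y", "z")]) - pl$centroid) * pl$normal)
  d2 <- sum((unlist(h[2, c("x", "y", "z")]) - pl$centroid) * pl$normal)
  expect_equal(d1, -d2, tolerance = 1e-9)
  expect_gt(abs(d1), 0.5)
})

test_that("bond lengths and geometry of placed hydrogens are ideal", {
  m <- place_hydrogens(structure_model(
    build_peptide(c("ALA", "LEU", "THR"), phi = -139, psi = 135)))
  a <- m$atoms
  h <- a[a$provenance == "placed", ]
  for (k in seq_len(nrow(h))) {
    heavy <- a[!is_hydrogen(a$element) & a$resno == h$resno[k], ]
    d <- sqrt((heavy$x - h$x[k])^2 + (heavy$y - h$y[k])^2 + (heavy$z - h$z[k])^2)
    parent <- heavy[which.min(d), ]
    expect_equal(min(d), if (parent$atom == "N") 1.01 else 1.09,
                 tolerance = 1e-6)
  }
})

test_that("distant residues yield no bonds; absent hydrogens are an error", {
  a1 <- build_peptide("ALA")
  a2 <- build_peptide("ALA", chain = "B")
  a2[, c("x", "y", "z")] <- a2[, c("x", "y", "z")] + 10
  m <- structure_model(rbind(a1, a2))
  expect_error(find_hbonds(m), "place_hydrogens")
  expect_equal(nrow(find_hbonds(place_hydrogens(m))), 0)
})

test_that("ideal helix yields the full i to i+4 backbone register", {
  hx <- build_element("helix", n = 12)
  m <- place_hydrogens(hx$model)
  bonds <- find_hbonds(m)
  bb <- bonds[bonds$bond_type == "NH_O" & bonds$donor_atom == "N" &
                bonds$acceptor_atom == "O", ]
  reg <- hx$ground_truth$register
  for (i in seq_len(nrow(reg))) {
    expect_true(any(bb$donor_resno == reg$donor_resno[i] &
                      bb$acceptor_resno == reg$acceptor_resno[i]),
                label = sprintf("helix bond %d->%d present",
                                reg$donor_resno[i], reg$acceptor_resno[i]))
  }
  # bond typing invariants
  expect_true(all(bonds$bond_type %in% c("NH_O", "CH_O")))
  don_el <- ifelse(bonds$bond_type == "CH_O", "C", "N")
  expect_equal(substr(bonds$donor_atom, 1, 1), don_el)
  expect_true(all(substr(bonds$acceptor_atom, 1, 1) == "O"))
})

test_that("antiparallel sheet register is recovered, including CA-H donors", {
  sh <- build_element("antiparallel_sheet", n = 6)
  m <- place_hydrogens(sh$model)
  bonds <- find_hbonds(m)
  bb <- bonds[bonds$bond_type == "NH_O" & bonds$donor_atom == "N", ]
  reg <- sh$ground_truth$register
  for (i in seq_len(nrow(reg))) {
    expect_true(any(bb$donor_chain == reg$donor_chain[i] &
                      bb$donor_resno == reg$donor_resno[i] &
                      bb$acceptor_chain == reg$acceptor_chain[i] &
                      bb$acceptor_resno == reg$acceptor_resno[i]),
                label = sprintf("sheet bond %s%d->%s%d present",
                                reg$donor_chain[i], reg$donor_resno[i],
                                reg$acceptor_chain[i], reg$acceptor_resno[i]))
  }
  ca <- bonds[bonds$donor_atom == "CA" & bonds$bond_type == "CH_O", ]
  expect_gt(nrow(ca), 0)   # inter-strand Calpha-H...O accompanies the sheet
})

test_that("criteria monotonicity: loosening never removes a bond", {
  sh <- build_element("antiparallel_sheet", n = 6)
  m <- place_hydrogens(sh$model)
  key <- function(b) paste(b$donor_chain, b$donor_resno, b$h_atom,
                           b$acceptor_chain, b$acceptor_resno, b$acceptor_atom)
  tight <- find_hbonds(m, hbond_criteria(ch_max_d_ha = 2.4, ch_max_d_da = 3.4,
                                         ch_min_theta = 130,
                                         nh_max_d_ha = 2.2, nh_max_d_da = 3.2,
                                         nh_min_theta = 140))
  mid <- find_hbonds(m)
  loose <- find_hbonds(m, hbond_criteria(ch_max_d_ha = 3.0, ch_max_d_da = 4.0,
                                         ch_min_theta = 100,
                                         nh_max_d_ha = 2.7, nh_max_d_da = 3.7,
                                         nh_min_theta = 110))
  expect_true(all(key(tight) %in% key(mid)))
  expect_true(all(key(mid) %in% key(loose)))
  expect_gte(nrow(loose), nrow(mid))
})

test_that("detection is deterministic: identical input, identical report", {
  sh <- build_element("beta_turn_I", subs = list("4" = "ILE"))
  m <- place_hydrogens(sh$model)
  b1 <- find_hbonds(m)
  b2 <- find_hbonds(m)
  expect_identical(b1, b2)
})

test_that("secondary structure: helix, hairpin and lone strand", {
  hx <- build_element("helix", n = 12)
  ss <- assign_secondary_structure(hx$model)
  expect_gte(sum(ss$ss == "H"), 8)

  hp <- build_element("beta_hairpin")
  ssh <- assign_secondary_structure(hp$model)
  expect_gte(mean(ssh$ss == hp$ground_truth$labels$ss), 0.9)
  expect_true(all(ssh$ss[c(5, 6)] == "T"))

  lone <- structure_model(build_peptide(rep("ALA", 6), phi = -139, psi = 135))
  ssl <- assign_secondary_structure(lone)
  expect_false(any(ssl$ss == "E"))   # no ladder partner, no strand

  short <- structure_model(build_peptide(rep("ALA", 2)))
  expect_true(all(assign_secondary_structure(short)$ss == "C"))
})

test_that("observed hydrogens win over placed ones", {
  hx <- build_element("helix", n = 6)
  m1 <- place_hydrogens(hx$model)
  # pretend the input had deposited deuteriums: re-placing keeps them
  a <- m1$atoms
  a$provenance[is_hydrogen(a$element)] <- "observed"
  a$element[is_hydrogen(a$element)] <- "D"
  m2 <- place_hydrogens(structure_model(a))
  expect_equal(attr(m2, "n_placed"), 0)
  bonds <- find_hbonds(m2)
  expect_true(all(bonds$h_provenance == "observed"))
})

test_that("capping motifs classify helix, turn and empty inputs", {
  # engineered Leu at i+4 of the helix contacts carbonyl(i)
  hx <- build_element("helix", n = 12, subs = list("9" = "LEU"),
                      chi = list("9" = c(-60, 180)))
  m <- place_hydrogens(hx$model)
  bonds <- find_hbonds(m)
  ss <- assign_secondary_structure(m, bonds = bonds)
  mot <- classify_motifs(bonds, ss)
  cap <- mot$bonds[mot$bonds$donor_resno == 9 &
                     mot$bonds$motif == "helix_sc_cap_i4", ]
  expect_gt(nrow(cap), 0)
  expect_equal(unique(cap$acceptor_resno), 5)
  expect_gt(mot$summary$count[mot$summary$motif == "helix_sc_cap_i4"], 0)

  # turn cap: side-chain bond coexists with the backbone i->i+3 bond
  tn <- build_element("beta_turn_I", subs = list("4" = "ILE"))
  mt <- place_hydrogens(tn$model)
  bt <- find_hbonds(mt)
  sst <- assign_secondary_structure(mt, bonds = bt)
  mot_t <- classify_motifs(bt, sst)
  tc <- mot_t$bonds[mot_t$bonds$motif == "turn_i_i3_sc_cap", , drop = FALSE]
  expect_gt(nrow(tc), 0)
  bbt <- bt[bt$bond_type == "NH_O" & bt$donor_atom == "N", ]
  for (k in seq_len(nrow(tc))) {
    expect_true(any(bbt$donor_resno == tc$acceptor_resno[k] + 3 &
                      bbt$acceptor_resno == tc$acceptor_resno[k]))
  }
  expect_equal(mot_t$turn_cap_fraction, 1)

  # empty bond set: all motif counts zero
  e <- classify_motifs(find_hbonds(place_hydrogens(structure_model(
    build_peptide("ALA"))), hbond_criteria(ch_max_d_ha = 0.1,
                                           nh_max_d_ha = 0.1)),
    assign_secondary_structure(structure_model(build_peptide("ALA"))))
  expect_true(all(e$summary$count == 0))
  expect_true(is.na(e$turn_cap_fraction))
})

test_that("helix C-terminal capping is distinguished from interior caps", {
  hx <- build_element("helix", n = 12, subs = list("12" = "LEU"),
                      chi = list("12" = c(-60, 180)))
  m <- place_hydrogens(hx$model)
  bonds <- find_hbonds(m)
  ss <- assign_secondary_structure(m, bonds = bonds)
  mot <- classify_motifs(bonds, ss)
  cc <- mot$bonds[mot$bonds$donor_resno == 12 &
                    mot$bonds$motif == "helix_c_cap", , drop = FALSE]
  expect_gt(nrow(cc), 0)
})
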