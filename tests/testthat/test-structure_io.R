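test_that("PDB reader represents all records and attaches ANISOU tensors", {
  path <- write_tripeptide_pdb()
  m <- read_structure(path)
  expect_s3_class(m, "StructureModel")
  expect_equal(nrow(m$atoms), 10)
  expect_equal(sum(!is.na(m$atoms$u11)), 2)
  # three residues, partitioned into classes totalling the residue count
  key <- paste(m$atoms$chain, m$atoms$resno, m$atoms$ins)
  cls <- tapply(m$atoms$class, key, `[`, 1)
  expect_equal(length(cls), 3)
  expect_equal(sum(cls == "polymer") + sum(cls == "ligand") +
                 sum(cls == "solvent"), length(cls))
  expect_equal(unname(cls[grepl("101", names(cls))]), "solvent")
  # U scaled from 1e-4 A^2: 1266 -> 0.1266, B_eq = 8pi^2/3 * 3 * 0.1266 ~ 10
  expect_equal(m$atoms$u11[m$atoms$atom == "CA" & m$atoms$resno == 1], 0.1266)
})

test_that("ANISOU without matching ATOM warns and is dropped", {
  lines <- tripeptide_pdb_lines()
  lines <- append(lines,
    "ANISOU   99  XX  ALA A   9     1000   1000   1000      0      0      0       C",
    after = length(lines) - 1)
  p <- tempfile(fileext = ".pdb")
  writeLines(lines, p)
  expect_warning(m <- read_structure(p), "without a matching ATOM")
  expect_equal(sum(!is.na(m$atoms$u11)), 2)
})

test_that("B_eq / b_iso disagreement warns but does not fail", {
  lines <- tripeptide_pdb_lines()
  i <- grep("^ANISOU", lines)[1]
  lines[i] <- sub("1266   1266   1266", "4000   4000   4000", lines[i])
  p <- tempfile(fileext = ".pdb")
  writeLines(lines, p)
  expect_warning(m <- read_structure(p), "B_eq")
  expect_equal(nrow(m$atoms), 10)
})

test_that("unreadable input produces a parse error naming the problem", {
  p <- tempfile(fileext = ".pdb")
  writeLines(c("this is", "not a structure"), p)
  expect_error(read_structure(p), "no ATOM/HETATM")
  expect_error(read_structure(tempfile(fileext = ".pdb")), "not found")
  pc <- tempfile(fileext = ".cif")
  writeLines("data_junk", pc)
  expect_error(read_structure(pc), "_atom_site")
})

test_that("alternate conformers are retained and resolved by occupancy", {
  p <- tempfile(fileext = ".pdb")
  writeLines(altloc_pdb_lines(), p)
  m <- read_structure(p)
  expect_equal(sum(m$atoms$atom == "CB"), 2)
  expect_setequal(m$atoms$altloc[m$atoms$atom == "CB"], c("A", "B"))
  m1 <- choose_conformer(m)
  # occupancies: A = 0.5 + 0.3, B = 0.5 + 0.7 -> B wins
  expect_equal(sum(m1$atoms$atom == "CB"), 1)
  expect_equal(m1$atoms$altloc[m1$atoms$atom == "CB"], "B")
  expect_equal(attr(m1, "altloc_choice")$altloc, "B")
  # exact occupancy tie goes to "A"
  a <- m$atoms
  a$occ[a$altloc != ""] <- 0.5
  m2 <- choose_conformer(structure_model(a))
  expect_equal(m2$atoms$altloc[m2$atoms$atom == "CB"], "A")
})

test_that("select_class returns exactly the class, optionally without H/D", {
  path <- write_tripeptide_pdb()
  m <- read_structure(path)
  expect_equal(nrow(select_class(m, "solvent")), 1)
  expect_equal(nrow(select_class(m, "ligand")), 0)
  expect_equal(nrow(select_class(m, "polymer")), 9)
  # water-only model has no polymer atoms
  w <- structure_model(m$atoms[m$atoms$class == "solvent", , drop = FALSE])
  expect_equal(nrow(select_class(w, "polymer")), 0)
  # deuterium counts as hydrogen
  a <- m$atoms
  a$atom[1] <- "D"; a$element[1] <- "D"
  md <- structure_model(a)
  expect_equal(nrow(select_class(md, "polymer", exclude_hydrogen = TRUE)), 8)
  expect_equal(nrow(select_class(md, "polymer", exclude_hydrogen = FALSE)), 9)
})

test_that("write/read round-trip preserves names, coordinates and tensors", {
  hx <- build_element("helix", n = 5)
  m <- attach_adps(hx$model, 0.3, c(1, 2, 3), 12)
  for (fmt in c("pdb", "mmcif")) {
    p <- tempfile(fileext = if (fmt == "pdb") ".pdb" else ".cif")
    write_structure(m, p, format = fmt)
    m2 <- read_structure(p, format = fmt)
    expect_equal(nrow(m2$atoms), nrow(m$atoms))
    expect_equal(m2$atoms$atom, m$atoms$atom)
    # absolute agreement at the written precision: 1e-3 A coordinates,
    # 1e-4 A^2 tensors
    expect_lt(max(abs(as.matrix(m2$atoms[, c("x", "y", "z")]) -
                        as.matrix(m$atoms[, c("x", "y", "z")]))), 6e-4)
    ucols <- c("u11", "u22", "u33", "u12", "u13", "u23")
    expect_lt(max(abs(as.matrix(m2$atoms[, ucols]) -
                        as.matrix(m$atoms[, ucols]))), 6e-5)
  }
})

test_that("residue views link polymer residues only across intact peptide bonds", {
  at <- build_peptide(rep("ALA", 4), phi = -139, psi = 135)
  m <- structure_model(at)
  v <- residue_views(m)
  expect_equal(length(v), 4)
  expect_equal(v[[2]]$prev, 1)
  expect_equal(v[[2]]$nxt, 3)
  expect_true(is.na(v[[1]]$prev))
  # break the chain after residue 2
  at2 <- at
  sel <- at2$resno > 2
  at2[sel, c("x", "y", "z")] <- at2[sel, c("x", "y", "z")] + 50
  v2 <- residue_views(structure_model(at2))
  expect_true(is.na(v2[[2]]$nxt))
  expect_equal(v2[[3]]$nxt, 4)
})
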