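# Coordinate I/O: fixed-column PDB and atom_site mmCIF, with anisotropic
# displacement (ANISOU / atom_site_anisotrop) records attached to their atoms.
# The in-memory model is a flat atom table plus residue-level classification;
# residue_views() lifts it into a structure -> chain -> residue -> atom
# hierarchy with polymer connectivity.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
WATER3 <- c("HOH", "DOD", "WAT", "H2O", "D2O")

ATOM_COLS <- c("record", "serial", "atom", "altloc", "resname", "chain",
               "resno", "ins", "x", "y", "z", "occ", "b", "element",
               "u11", "u22", "u33", "u12", "u13", "u23")

empty_atoms <- function() {
  data.frame(record = character(), serial = integer(), atom = character(),
             altloc = character(), resname = character(), chain = character(),
             resno = integer(), ins = character(),
             x = numeric(), y = numeric(), z = numeric(),
             occ = numeric(), b = numeric(), element = character(),
             u11 = numeric(), u22 = numeric(), u33 = numeric(),
             u12 = numeric(), u13 = numeric(), u23 = numeric(),
             stringsAsFactors = FALSE)
}

#' Construct a StructureModel from an atom table
#'
#' @param atoms data.frame with the canonical atom columns (see
#'   [read_structure()]); missing uij columns are filled with `NA`.
#' @param entry_id identifier string used in reports.
#' @return a `StructureModel`: list with `entry_id`, `atoms` (one row per
#'   atom, residue class in column `class`).
#' @export
structure_model <- function(atoms, entry_id = "XXXX") {
  for (cn in ATOM_COLS) {
    if (!cn %in% names(atoms)) {
      atoms[[cn]] <- if (cn %in% c("x", "y", "z", "occ", "b",
                                   "u11", "u22", "u33", "u12", "u13", "u23"))
        NA_real_ else if (cn %in% c("serial", "resno")) NA_integer_ else ""
    }
  }
  extra <- setdiff(names(atoms), c(ATOM_COLS, "class"))
  atoms <- atoms[, c(ATOM_COLS, extra)]
  atoms$class <- classify_residues(atoms)
  structure(list(entry_id = entry_id, atoms = atoms), class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  a <- x$atoms
  rk <- residue_key(a)
  cls <- tapply(a$class, rk, `[`, 1)
  cat(sprintf("StructureModel %s: %d atoms, %d residues (%d polymer, %d ligand, %d solvent), %d chains\n",
              x$entry_id, nrow(a), length(cls),
              sum(cls == "polymer"), sum(cls == "ligand"), sum(cls == "solvent"),
              length(unique(a$chain))))
  invisible(x)
}

residue_key <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$ins, sep = "|")
}

#' Classify residues as polymer, ligand or solvent
#'
#' Standard amino acids are polymer, waters are solvent, every other HETATM
#' group is ligand. The partition is total: each residue gets exactly one
#' class.
#' @noRd
classify_residues <- function(atoms) {
  ifelse(atoms$resname %in% AA3, "polymer",
         ifelse(atoms$resname %in% WATER3, "solvent", "ligand"))
}

#' Treat deuterium as hydrogen throughout
#' @param element character vector of element symbols.
#' @return logical vector.
#' @export
is_hydrogen <- function(element) toupper(element) %in% c("H", "D")

guess_element <- function(name) {
  nm <- gsub("[^A-Za-z]", "", name)
  first <- toupper(substr(nm, 1, 1))
  # names beginning with a digit (e.g. 1HB2) are hydrogens by PDB convention
  lead_digit <- grepl("^[0-9]", trimws(name))
  ifelse(lead_digit | first %in% c("H", "D"), ifelse(first == "D", "D", "H"), first)
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))
int_or_na <- function(x) suppressWarnings(as.integer(x))

# ---------------------------------------------------------------------------
# PDB reader

read_pdb_atoms <- function(lines, path = "<pdb>") {
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  is_aniso <- startsWith(lines, "ANISOU")
  al <- lines[is_atom]
  if (length(al) == 0) {
    stop(sprintf("parse error in %s: no ATOM/HETATM records found", path),
         call. = FALSE)
  }
  f <- function(v, a, b) substr(v, a, b)
  atoms <- data.frame(
    record = trimws(f(al, 1, 6)),
    serial = int_or_na(f(al, 7, 11)),
    atom = trimws(f(al, 13, 16)),
    altloc = trimws(f(al, 17, 17)),
    resname = trimws(f(al, 18, 20)),
    chain = trimws(f(al, 22, 22)),
    resno = int_or_na(f(al, 23, 26)),
    ins = trimws(f(al, 27, 27)),
    x = num_or_na(f(al, 31, 38)),
    y = num_or_na(f(al, 39, 46)),
    z = num_or_na(f(al, 47, 54)),
    occ = num_or_na(f(al, 55, 60)),
    b = num_or_na(f(al, 61, 66)),
    element = trimws(f(al, 77, 78)),
    stringsAsFactors = FALSE
  )
  bad <- which(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))
  if (length(bad) > 0) {
    stop(sprintf("parse error in %s: non-numeric coordinates on ATOM record line %d",
                 path, which(is_atom)[bad[1]]), call. = FALSE)
  }
  blank_el <- atoms$element == ""
  atoms$element[blank_el] <- guess_element(atoms$atom[blank_el])
  for (u in c("u11", "u22", "u33", "u12", "u13", "u23")) atoms[[u]] <- NA_real_

  if (any(is_aniso)) {
    an <- lines[is_aniso]
    akey <- paste(trimws(f(an, 13, 16)), trimws(f(an, 17, 17)),
                  trimws(f(an, 18, 20)), trimws(f(an, 22, 22)),
                  trimws(f(an, 23, 26)), trimws(f(an, 27, 27)), sep = "|")
    atkey <- paste(atoms$atom, atoms$altloc, atoms$resname, atoms$chain,
                   atoms$resno, atoms$ins, sep = "|")
    idx <- match(akey, atkey)
    orphans <- sum(is.na(idx))
    if (orphans > 0) {
      warning(sprintf("%s: %d ANISOU record(s) without a matching ATOM were dropped",
                      path, orphans), call. = FALSE)
    }
    ucols <- list(u11 = c(29, 35), u22 = c(36, 42), u33 = c(43, 49),
                  u12 = c(50, 56), u13 = c(57, 63), u23 = c(64, 70))
    keep <- !is.na(idx)
    for (u in names(ucols)) {
      vals <- num_or_na(f(an, ucols[[u]][1], ucols[[u]][2])) / 1e4
      atoms[[u]][idx[keep]] <- vals[keep]
    }
  }
  atoms
}

# ---------------------------------------------------------------------------
# mmCIF reader (atom_site and atom_site_anisotrop categories only)

cif_tokens <- function(line) {
  # bare tokens plus single/double-quoted strings; comments stripped
  m <- gregexpr("'[^']*'|\"[^\"]*\"|[^\\s]+", line, perl = TRUE)[[1]]
  if (m[1] == -1) return(character())
  tok <- regmatches(line, list(m))[[1]]
  tok <- tok[!startsWith(tok, "#")]
  gsub("^['\"]|['\"]$", "", tok)
}

cif_read_loop <- function(lines, i) {
  # lines[i] == "loop_"; returns list(fields, rows, next_i)
  n <- length(lines)
  i <- i + 1
  fields <- character()
  while (i <= n && grepl("^_", trimws(lines[i]))) {
    fields <- c(fields, strsplit(trimws(lines[i]), "[[:space:]]+")[[1]][1])
    i <- i + 1
  }
  vals <- character()
  while (i <= n) {
    l <- trimws(lines[i])
    if (l == "" || startsWith(l, "#") || startsWith(l, "loop_") ||
        startsWith(l, "_") || startsWith(l, "data_")) break
    vals <- c(vals, cif_tokens(lines[i]))
    i <- i + 1
  }
  nf <- length(fields)
  nrow <- length(vals) %/% nf
  rows <- matrix(vals[seq_len(nrow * nf)], ncol = nf, byrow = TRUE)
  colnames(rows) <- fields
  list(fields = fields, rows = rows, next_i = i)
}

cif_col <- function(rows, primary, fallback = NULL) {
  if (primary %in% colnames(rows)) return(rows[, primary])
  if (!is.null(fallback) && fallback %in% colnames(rows)) return(rows[, fallback])
  rep(NA_character_, nrow(rows))
}

read_mmcif_atoms <- function(lines, path = "<cif>") {
  n <- length(lines)
  site <- NULL
  aniso <- NULL
  i <- 1
  while (i <= n) {
    if (trimws(lines[i]) == "loop_") {
      lp <- cif_read_loop(lines, i)
      if (any(startsWith(lp$fields, "_atom_site_anisotrop."))) {
        aniso <- lp$rows
      } else if (any(startsWith(lp$fields, "_atom_site."))) {
        site <- lp$rows
      }
      i <- lp$next_i
    } else {
      i <- i + 1
    }
  }
  if (is.null(site)) {
    stop(sprintf("parse error in %s: no _atom_site loop category found", path),
         call. = FALSE)
  }
  blank_if_dot <- function(x) ifelse(x %in% c(".", "?") | is.na(x), "", x)
  atoms <- data.frame(
    record = ifelse(cif_col(site, "_atom_site.group_PDB") == "HETATM", "HETATM", "ATOM"),
    serial = int_or_na(cif_col(site, "_atom_site.id")),
    atom = blank_if_dot(cif_col(site, "_atom_site.auth_atom_id", "_atom_site.label_atom_id")),
    altloc = blank_if_dot(cif_col(site, "_atom_site.label_alt_id")),
    resname = blank_if_dot(cif_col(site, "_atom_site.auth_comp_id", "_atom_site.label_comp_id")),
    chain = blank_if_dot(cif_col(site, "_atom_site.auth_asym_id", "_atom_site.label_asym_id")),
    resno = int_or_na(cif_col(site, "_atom_site.auth_seq_id", "_atom_site.label_seq_id")),
    ins = blank_if_dot(cif_col(site, "_atom_site.pdbx_PDB_ins_code")),
    x = num_or_na(cif_col(site, "_atom_site.Cartn_x")),
    y = num_or_na(cif_col(site, "_atom_site.Cartn_y")),
    z = num_or_na(cif_col(site, "_atom_site.Cartn_z")),
    occ = num_or_na(cif_col(site, "_atom_site.occupancy")),
    b = num_or_na(cif_col(site, "_atom_site.B_iso_or_equiv")),
    element = blank_if_dot(cif_col(site, "_atom_site.type_symbol")),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(atoms$x))) {
    stop(sprintf("parse error in %s: non-numeric Cartn_x in _atom_site", path),
         call. = FALSE)
  }
  blank_el <- atoms$element == ""
  atoms$element[blank_el] <- guess_element(atoms$atom[blank_el])
  for (u in c("u11", "u22", "u33", "u12", "u13", "u23")) atoms[[u]] <- NA_real_
  if (!is.null(aniso)) {
    idx <- match(int_or_na(cif_col(aniso, "_atom_site_anisotrop.id")), atoms$serial)
    orphans <- sum(is.na(idx))
    if (orphans > 0) {
      warning(sprintf("%s: %d atom_site_anisotrop record(s) without a matching atom_site were dropped",
                      path, orphans), call. = FALSE)
    }
    umap <- c(u11 = "_atom_site_anisotrop.U[1][1]", u22 = "_atom_site_anisotrop.U[2][2]",
              u33 = "_atom_site_anisotrop.U[3][3]", u12 = "_atom_site_anisotrop.U[1][2]",
              u13 = "_atom_site_anisotrop.U[1][3]", u23 = "_atom_site_anisotrop.U[2][3]")
    keep <- !is.na(idx)
    for (u in names(umap)) {
      atoms[[u]][idx[keep]] <- num_or_na(cif_col(aniso, umap[[u]]))[keep]
    }
  }
  atoms
}

# ---------------------------------------------------------------------------

#' Read a structure from a PDB or mmCIF file
#'
#' All ATOM/HETATM (or atom_site) records are kept, including alternate
#' conformers; ANISOU / atom_site_anisotrop tensors are attached to their
#' atoms. Residues are classified polymer / ligand / solvent.
#'
#' If anisotropic tensors are present, the isotropic-equivalent
#' \eqn{B_{eq} = (8\pi^2/3)\,\mathrm{tr}(U)} is checked against the recorded
#' isotropic B; disagreements beyond 1\% raise a warning (never an error).
#'
#' @param path file path.
#' @param format one of `"pdb"`, `"mmcif"`, `"auto"` (extension-based,
#'   `.cif`/`.mmcif` are mmCIF, everything else PDB).
#' @return a `StructureModel` (see [structure_model()]).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  lines <- readLines(path, warn = FALSE)
  atoms <- if (format == "pdb") read_pdb_atoms(lines, path) else read_mmcif_atoms(lines, path)
  entry <- toupper(tools::file_path_sans_ext(basename(path)))
  m <- structure_model(atoms, entry_id = entry)
  check_beq_consistency(m$atoms, path)
  m
}

check_beq_consistency <- function(atoms, path) {
  has_u <- !is.na(atoms$u11)
  if (!any(has_u)) return(invisible())
  tr <- atoms$u11[has_u] + atoms$u22[has_u] + atoms$u33[has_u]
  beq <- (8 * pi^2 / 3) * tr
  b <- atoms$b[has_u]
  ok <- is.na(b) | b <= 0 | abs(beq - b) <= 0.01 * pmax(b, .Machine$double.eps)
  nbad <- sum(!ok)
  if (nbad > 0) {
    warning(sprintf("%s: B_eq from uij disagrees with b_iso by >1%% for %d atom(s)",
                    path, nbad), call. = FALSE)
  }
  invisible()
}

#' Write a StructureModel to disk
#'
#' Deterministic output: identical models produce byte-identical files.
#' Coordinates are written to 3 decimals, uij tensors to 1e-4 A^2 (the PDB
#' ANISOU quantum).
#'
#' @param model a `StructureModel`.
#' @param path output path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (from extension).
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  a <- model$atoms
  a$serial <- seq_len(nrow(a))
  lines <- if (format == "pdb") format_pdb(a, model$entry_id) else format_mmcif(a, model$entry_id)
  writeLines(lines, path)
  invisible(path)
}

pdb_atom_name <- function(name, element) {
  # element columns 13-14: one-letter elements start in column 14
  ifelse(nchar(name) >= 4 | nchar(element) == 2,
         sprintf("%-4s", name), sprintf(" %-3s", name))
}

format_pdb <- function(a, entry_id) {
  nm <- pdb_atom_name(a$atom, a$element)
  atom_lines <- sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                        a$record, a$serial, nm, a$altloc, a$resname, a$chain,
                        a$resno, a$ins, a$x, a$y, a$z, a$occ, a$b,
                        sprintf("%2s", a$element))
  has_u <- !is.na(a$u11)
  out <- character(0)
  header <- sprintf("HEADER    SYNTHETIC/ANALYSIS FIXTURE%24s%4s", "", substr(entry_id, 1, 4))
  for (i in seq_len(nrow(a))) {
    out <- c(out, atom_lines[i])
    if (has_u[i]) {
      out <- c(out, sprintf("ANISOU%5d %s%1s%-3s %1s%4d%1s %7d%7d%7d%7d%7d%7d      %2s",
                            a$serial[i], nm[i], a$altloc[i], a$resname[i],
                            a$chain[i], a$resno[i], a$ins[i],
                            round(a$u11[i] * 1e4), round(a$u22[i] * 1e4),
                            round(a$u33[i] * 1e4), round(a$u12[i] * 1e4),
                            round(a$u13[i] * 1e4), round(a$u23[i] * 1e4),
                            sprintf("%2s", a$element[i])))
    }
  }
  c(header, out, "END")
}

cif_quote <- function(x) ifelse(x == "", ".", ifelse(grepl("[[:space:]']", x), sprintf("\"%s\"", x), x))

format_mmcif <- function(a, entry_id) {
  head <- c(sprintf("data_%s", entry_id), "#", "loop_",
            "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
            "_atom_site.label_atom_id", "_atom_site.label_alt_id",
            "_atom_site.label_comp_id", "_atom_site.auth_asym_id",
            "_atom_site.auth_seq_id", "_atom_site.pdbx_PDB_ins_code",
            "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
            "_atom_site.occupancy", "_atom_site.B_iso_or_equiv")
  rows <- sprintf("%-6s %d %s %s %s %s %s %d %s %.3f %.3f %.3f %.2f %.2f",
                  a$record, a$serial, cif_quote(a$element), cif_quote(a$atom),
                  cif_quote(a$altloc), a$resname, cif_quote(a$chain), a$resno,
                  cif_quote(a$ins), a$x, a$y, a$z, a$occ, a$b)
  out <- c(head, rows, "#")
  has_u <- which(!is.na(a$u11))
  if (length(has_u) > 0) {
    ah <- c("loop_", "_atom_site_anisotrop.id", "_atom_site_anisotrop.U[1][1]",
            "_atom_site_anisotrop.U[2][2]", "_atom_site_anisotrop.U[3][3]",
            "_atom_site_anisotrop.U[1][2]", "_atom_site_anisotrop.U[1][3]",
            "_atom_site_anisotrop.U[2][3]")
    arows <- sprintf("%d %.4f %.4f %.4f %.4f %.4f %.4f",
                     a$serial[has_u], a$u11[has_u], a$u22[has_u], a$u33[has_u],
                     a$u12[has_u], a$u13[has_u], a$u23[has_u])
    out <- c(out, ah, arows, "#")
  }
  out
}

# ---------------------------------------------------------------------------
# Selections and residue views

#' Select atoms of one residue class
#'
#' @param model a `StructureModel`.
#' @param class `"polymer"`, `"ligand"` or `"solvent"`.
#' @param exclude_hydrogen drop H and D atoms (default `TRUE`).
#' @return atom data.frame (possibly empty).
#' @export
select_class <- function(model, class = c("polymer", "ligand", "solvent"),
                         exclude_hydrogen = TRUE) {
  class <- match.arg(class)
  a <- model$atoms[model$atoms$class == class, , drop = FALSE]
  if (exclude_hydrogen) a <- a[!is_hydrogen(a$element), , drop = FALSE]
  a
}

#' Reduce alternate conformers to a single conformer per residue
#'
#' Keeps blank-altloc atoms plus, per residue, the altloc with the highest
#' total occupancy (ties broken alphabetically, so "A" wins). The chosen
#' altloc per disordered residue is recorded in `attr(, "altloc_choice")`.
#'
#' @param model a `StructureModel`.
#' @return a `StructureModel` with at most one conformer per residue.
#' @export
choose_conformer <- function(model) {
  a <- model$atoms
  alt <- a$altloc != ""
  if (!any(alt)) {
    attr(model, "altloc_choice") <- data.frame(residue = character(),
                                               altloc = character())
    return(model)
  }
  key <- residue_key(a)
  choice <- vapply(split(seq_len(nrow(a))[alt], key[alt]), function(ix) {
    occ <- tapply(a$occ[ix], a$altloc[ix], sum)
    names(occ)[order(-occ, names(occ))][1]
  }, character(1))
  keep <- !alt | a$altloc == choice[match(key, names(choice))]
  out <- structure_model(a[keep, , drop = FALSE], entry_id = model$entry_id)
  attr(out, "altloc_choice") <- data.frame(residue = names(choice),
                                           altloc = unname(choice))
  out
}

#' Residue-level view of a model
#'
#' Groups atoms by residue (in file order, per chain) and links consecutive
#' polymer residues when the peptide C(i)-N(i+1) distance is at most 2.0
#' angstrom.
#'
#' @param model a `StructureModel` (run [choose_conformer()] first if the
#'   model has alternate conformers).
#' @param class restrict to one residue class, default `"polymer"`; `NULL`
#'   for all.
#' @return list of `ResidueView` objects: `chain`, `resno`, `ins`, `resname`,
#'   `class`, `xyz` (matrix, rownames = atom names), `element` (named),
#'   `prev`/`nxt` (index into the list or `NA`).
#' @export
residue_views <- function(model, class = "polymer") {
  a <- model$atoms
  if (!is.null(class)) a <- a[a$class %in% class, , drop = FALSE]
  if (nrow(a) == 0) return(list())
  key <- residue_key(a)
  ord <- !duplicated(key)
  keys <- key[ord]
  idx <- split(seq_len(nrow(a)), factor(key, levels = keys))
  views <- lapply(seq_along(idx), function(k) {
    ix <- idx[[k]]
    xyz <- as.matrix(a[ix, c("x", "y", "z")])
    rownames(xyz) <- a$atom[ix]
    structure(list(
      chain = a$chain[ix[1]], resno = a$resno[ix[1]], ins = a$ins[ix[1]],
      resname = a$resname[ix[1]], class = a$class[ix[1]],
      xyz = xyz, element = stats::setNames(a$element[ix], a$atom[ix]),
      rows = ix, prev = NA_integer_, nxt = NA_integer_
    ), class = "ResidueView")
  })
  # polymer connectivity within each chain, in file order
  for (k in seq_along(views)[-1]) {
    v0 <- views[[k - 1]]
    v1 <- views[[k]]
    if (v0$chain != v1$chain) next
    if (v0$class != "polymer" || v1$class != "polymer") next
    c0 <- res_atom(v0, "C")
    n1 <- res_atom(v1, "N")
    if (is.null(c0) || is.null(n1)) next
    if (vnorm(n1 - c0) <= 2.0) {
      views[[k - 1]]$nxt <- k
      views[[k]]$prev <- k - 1
    }
  }
  views
}

#' Coordinates of a named atom in a ResidueView (NULL when absent)
#' @param res a `ResidueView`.
#' @param name atom name, PDB convention.
#' @export
res_atom <- function(res, name) {
  i <- match(name, rownames(res$xyz))
  if (is.na(i)) return(NULL)
  res$xyz[i, ]
}

#' Short residue label for reports, e.g. "A/ARG78"
#' @noRd
res_label <- function(res) {
  sprintf("%s/%s%d%s", res$chain, res$resname, res$resno, res$ins)
}

#' @export
print.ResidueView <- function(x, ...) {
  cat(sprintf("ResidueView %s (%s, %d atoms)\n", res_label(x), x$class, nrow(x$xyz)))
  invisible(x)
}
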