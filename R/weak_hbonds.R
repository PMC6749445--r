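# Riding-hydrogen placement, N-H...O / C-H...O hydrogen-bond detection, a
# hydrogen-bond-pattern secondary-structure assignment, and classification of
# side-chain C-H...O bonds into capping motifs.

H_BOND_MAX <- 1.3      # H considered bonded to the nearest heavy atom within this
CH_BOND_LEN <- 1.09
NH_BOND_LEN <- 1.01

# sp2 carbons and nitrogens by residue (backbone C is always sp2 and never
# protonated). Everything else defaults to sp3.
SP2_TABLE <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  ASN = "CG", ASP = "CG", GLN = "CD", GLU = "CD",
  ARG = c("CZ", "NE", "NH1", "NH2")
)

residue_connectivity <- function(res) {
  # heavy-atom bonds within a residue by distance (S gets a longer reach)
  heavy <- which(!is_hydrogen(res$element))
  nm <- rownames(res$xyz)[heavy]
  xyz <- res$xyz[heavy, , drop = FALSE]
  el <- res$element[heavy]
  nb <- stats::setNames(vector("list", length(nm)), nm)
  if (length(nm) < 2) return(nb)
  d <- as.matrix(stats::dist(xyz))
  cut <- outer(el %in% "S", el %in% "S", `|`) * 0.15 + 1.8
  for (i in seq_along(nm)) {
    nb[[nm[i]]] <- nm[d[i, ] > 0 & d[i, ] <= cut[i, ]]
  }
  nb
}

expected_hydrogens <- function(res, nb, has_prev, has_next) {
  # how many H each C (and the backbone N) should carry
  out <- list()
  nm <- names(nb)
  for (a in nm) {
    el <- toupper(res$element[[a]])
    k <- length(nb[[a]])
    if (a == "C") next                       # carbonyl carbon, never protonated
    if (el == "C") {
      sp2 <- a %in% SP2_TABLE[[res$resname]]
      val <- if (sp2) 3 else 4
      nh <- val - k
      if (nh > 0) out[[a]] <- nh
    } else if (a == "N" && res$resname != "PRO") {
      # backbone amide: one riding H (also at the N-terminus, where the
      # full ammonium is deliberately not modelled)
      nh <- 3 - k - (if (has_prev) 1 else 0)
      if (nh > 0) out[[a]] <- 1
    }
  }
  out
}

hydrogen_names <- function(parent, n) {
  if (parent == "N") return("H")
  suffix <- substring(parent, 2)
  if (n == 1) paste0("H", suffix) else paste0("H", suffix, seq_len(n))
}

place_h_on_atom <- function(res, parent, n_h, nb, prev_c) {
  x <- res_atom(res, parent)
  el <- toupper(res$element[[parent]])
  blen <- if (el == "N") NH_BOND_LEN else CH_BOND_LEN
  neigh <- nb[[parent]]
  npos <- lapply(neigh, function(nn) res_atom(res, nn))
  if (parent == "N" && !is.null(prev_c)) npos <- c(npos, list(prev_c))
  k <- length(npos)
  units <- lapply(npos, function(p) vunit(p - x))

  if (k >= 2 && n_h == 1) {
    # sp3 CH with 3 neighbours, sp2 CH / amide NH with 2: external bisector
    s <- Reduce(`+`, units)
    return(list(x + blen * vunit(-s)))
  }
  if (k == 2 && n_h == 2) {
    # methylene: both H in the plane bisecting the two substituents
    b <- vunit(-(units[[1]] + units[[2]]))
    p <- vunit(vcross(units[[1]], units[[2]]))
    half <- 54.75 * pi / 180              # half the ideal H-C-H angle
    return(list(x + blen * (cos(half) * b + sin(half) * p),
                x + blen * (cos(half) * b - sin(half) * p)))
  }
  if (k == 1 && n_h == 3) {
    # methyl rotor, staggered relative to the preceding bond
    r1 <- neigh[1]
    ref_nm <- setdiff(nb[[r1]], parent)
    ref <- if (length(ref_nm) > 0) res_atom(res, sort(ref_nm)[1]) else NULL
    if (is.null(ref) && r1 == "CA") ref <- res_atom(res, "N")
    if (is.null(ref)) ref <- res_atom(res, r1) + c(1, 0, 0)
    return(lapply(c(180, -60, 60), function(tor) {
      place_internal(ref, res_atom(res, r1), x, blen, 109.47, tor)
    }))
  }
  if (k == 1 && n_h == 1) {
    # N-terminal amide: single H anti to the carbonyl carbon
    r1 <- neigh[1]
    ref_nm <- setdiff(nb[[r1]], parent)
    ref <- if (length(ref_nm) > 0) res_atom(res, sort(ref_nm)[1]) else
      res_atom(res, r1) + c(0, 0, 1)
    return(list(place_internal(ref, res_atom(res, r1), x, blen, 119, 180)))
  }
  if (k == 1 && n_h == 2) {
    # sp2 =CH2 (none in the standard set) or degenerate sp3: place like a
    # methylene using an arbitrary in-frame reference
    r1 <- neigh[1]
    ref_nm <- setdiff(nb[[r1]], parent)
    ref <- if (length(ref_nm) > 0) res_atom(res, sort(ref_nm)[1]) else
      res_atom(res, r1) + c(0, 0, 1)
    return(lapply(c(0, 180), function(tor) {
      place_internal(ref, res_atom(res, r1), x, blen, 120, tor)
    }))
  }
  NULL
}

#' Place riding hydrogens on carbon and backbone-amide donors
#'
#' Every sp3/sp2 C-H and backbone N-H is built at ideal geometry (C-H 1.09,
#' N-H 1.01 angstrom; tetrahedral or trigonal frames from the heavy atoms;
#' methyl rotors staggered relative to the preceding bond). Prolines get no
#' amide H; side-chain N-H and O-H are used when observed but are not built.
#' Placed atoms carry `provenance == "placed"`.
#'
#' @param model a `StructureModel` (single conformer; run
#'   [choose_conformer()] first if needed).
#' @param mode `"keep_existing"` (default; parents that already carry an
#'   observed H are left alone) or `"rebuild_all"` (observed H on C/backbone
#'   N are discarded and rebuilt).
#' @return the model with hydrogen atoms appended (provenance column set).
#' @export
place_hydrogens <- function(model, mode = c("keep_existing", "rebuild_all")) {
  mode <- match.arg(mode)
  atoms <- model$atoms
  if (is.null(atoms$provenance)) atoms$provenance <- "observed"
  views <- residue_views(model, class = "polymer")
  new_rows <- list()
  drop_rows <- integer()

  for (v in views) {
    if (!v$resname %in% c(AA3)) next
    nb <- residue_connectivity(v)
    if (length(nb) == 0) next
    prev_c <- if (!is.na(v$prev)) res_atom(views[[v$prev]], "C") else NULL
    exp_h <- expected_hydrogens(v, nb, has_prev = !is.na(v$prev),
                                has_next = !is.na(v$nxt))
    if (length(exp_h) == 0) next
    # existing H per parent (nearest heavy within bonding distance)
    hmask <- is_hydrogen(v$element)
    h_parent <- character(0)
    if (any(hmask)) {
      hn <- rownames(v$xyz)[hmask]
      heavy_nm <- rownames(v$xyz)[!hmask]
      h_parent <- vapply(hn, function(h) {
        d <- sqrt(colSums((t(v$xyz[heavy_nm, , drop = FALSE]) -
                             res_atom(v, h))^2))
        if (min(d) <= H_BOND_MAX) heavy_nm[which.min(d)] else NA_character_
      }, character(1))
    }
    for (parent in names(exp_h)) {
      existing <- names(h_parent)[!is.na(h_parent) & h_parent == parent]
      if (length(existing) > 0) {
        if (mode == "keep_existing") next
        drop_rows <- c(drop_rows, v$rows[match(existing, rownames(v$xyz))])
      }
      pos <- place_h_on_atom(v, parent, exp_h[[parent]], nb, prev_c)
      if (is.null(pos)) next
      nms <- hydrogen_names(parent, length(pos))
      template <- atoms[v$rows[match(parent, rownames(v$xyz))], ]
      for (q in seq_along(pos)) {
        r <- template
        r$atom <- nms[q]
        r$element <- "H"
        r[c("x", "y", "z")] <- as.list(pos[[q]])
        r[c("u11", "u22", "u33", "u12", "u13", "u23")] <- NA_real_
        r$provenance <- "placed"
        new_rows[[length(new_rows) + 1]] <- r
      }
    }
  }
  if (length(drop_rows) > 0) atoms <- atoms[-drop_rows, , drop = FALSE]
  if (length(new_rows) > 0) atoms <- rbind(atoms, do.call(rbind, new_rows))
  n_placed <- length(new_rows)
  out <- structure_model(atoms, entry_id = model$entry_id)
  attr(out, "n_placed") <- n_placed
  out
}

#' Hydrogen-bond geometric criteria
#'
#' The source analysis states no numeric criteria; these defaults follow
#' common weak-hydrogen-bond practice and are this package's own policy.
#'
#' @param ch_max_d_ha,ch_max_d_da,ch_min_theta C-H...O: max H...A (2.8),
#'   max D...A (3.8) angstrom, min D-H-A angle (110 degrees).
#' @param nh_max_d_ha,nh_max_d_da,nh_min_theta N-H...O: 2.5 / 3.5 / 120.
#' @return named list of thresholds.
#' @export
hbond_criteria <- function(ch_max_d_ha = 2.8, ch_max_d_da = 3.8,
                           ch_min_theta = 110, nh_max_d_ha = 2.5,
                           nh_max_d_da = 3.5, nh_min_theta = 120) {
  list(ch_max_d_ha = ch_max_d_ha, ch_max_d_da = ch_max_d_da,
       ch_min_theta = ch_min_theta, nh_max_d_ha = nh_max_d_ha,
       nh_max_d_da = nh_max_d_da, nh_min_theta = nh_min_theta)
}

empty_bonds <- function() {
  data.frame(donor_chain = character(), donor_resno = integer(),
             donor_ins = character(), donor_resname = character(),
             donor_atom = character(), h_atom = character(),
             h_provenance = character(),
             acceptor_chain = character(), acceptor_resno = integer(),
             acceptor_ins = character(), acceptor_resname = character(),
             acceptor_atom = character(),
             d_HA = numeric(), d_DA = numeric(), theta_DHA = numeric(),
             bond_type = character(), donor_class = character(),
             acceptor_class = character(), motif = character(),
             stringsAsFactors = FALSE)
}

#' Detect N-H...O and C-H...O hydrogen bonds
#'
#' Emits every donor-H / acceptor-oxygen pair satisfying the criteria.
#' Donors are hydrogens bonded to C or N; acceptors are oxygens of any
#' residue class. Intra-residue pairs and the covalent amide-carbonyl
#' 1-3 pair (N-H of residue i against O of residue i-1) are excluded.
#' Output order is deterministic (donor, acceptor, d_HA).
#'
#' @param model a `StructureModel` with hydrogens (observed or from
#'   [place_hydrogens()]).
#' @param criteria list from [hbond_criteria()].
#' @return data.frame of bonds (one row each): donor/H/acceptor identities,
#'   d_HA, d_DA, theta_DHA, bond_type (`NH_O`/`CH_O`), donor_class
#'   (`main_chain`/`side_chain`), acceptor_class (`main_chain_carbonyl`,
#'   `side_chain_O`, `water`, `ligand_O`), motif (`NA` until
#'   [classify_motifs()]).
#' @export
find_hbonds <- function(model, criteria = hbond_criteria()) {
  a <- model$atoms
  if (is.null(a$provenance)) a$provenance <- "observed"
  hmask <- is_hydrogen(a$element)
  if (!any(hmask)) {
    stop("no hydrogen atoms present; run place_hydrogens() first", call. = FALSE)
  }
  heavy <- which(!hmask)
  hx <- as.matrix(a[hmask, c("x", "y", "z")])
  hidx <- which(hmask)

  # donor parent: nearest heavy atom within bonding distance, same residue
  hkey <- residue_key(a)[hmask]
  heavykey <- residue_key(a)[heavy]
  parent <- rep(NA_integer_, length(hidx))
  for (q in seq_along(hidx)) {
    cand <- heavy[heavykey == hkey[q]]
    if (length(cand) == 0) next
    d <- sqrt((a$x[cand] - hx[q, 1])^2 + (a$y[cand] - hx[q, 2])^2 +
                (a$z[cand] - hx[q, 3])^2)
    if (min(d) <= H_BOND_MAX) parent[q] <- cand[which.min(d)]
  }
  pel <- toupper(a$element[parent])
  donor_ok <- !is.na(parent) & pel %in% c("C", "N")
  acc <- which(toupper(a$element) == "O")
  if (sum(donor_ok) == 0 || length(acc) == 0) return(empty_bonds())

  hq <- which(donor_ok)
  max_dha <- max(criteria$ch_max_d_ha, criteria$nh_max_d_ha)
  res_index <- polymer_residue_index(a)

  rows <- vector("list", 256)
  nr <- 0
  for (q in hq) {
    hi <- hidx[q]
    pi <- parent[q]
    d_ha <- sqrt((a$x[acc] - a$x[hi])^2 + (a$y[acc] - a$y[hi])^2 +
                   (a$z[acc] - a$z[hi])^2)
    cand <- acc[d_ha <= max_dha]
    dha <- d_ha[d_ha <= max_dha]
    if (length(cand) == 0) next
    dkey <- residue_key(a)[pi]
    for (w in seq_along(cand)) {
      ai <- cand[w]
      akey <- residue_key(a)[ai]
      if (akey == dkey) next
      # exclude the covalent amide/carbonyl 1-3 pair
      if (a$atom[pi] == "N" && a$atom[ai] == "O") {
        di <- res_index[dkey]; aj <- res_index[akey]
        if (!is.na(di) && !is.na(aj) && a$chain[pi] == a$chain[ai] &&
            aj == di - 1) next
      }
      ch <- pel[q] == "C"
      d_da <- vnorm(c(a$x[ai] - a$x[pi], a$y[ai] - a$y[pi], a$z[ai] - a$z[pi]))
      th <- angle3(c(a$x[pi], a$y[pi], a$z[pi]),
                   c(a$x[hi], a$y[hi], a$z[hi]),
                   c(a$x[ai], a$y[ai], a$z[ai]))
      ok <- if (ch) {
        dha[w] <= criteria$ch_max_d_ha && d_da <= criteria$ch_max_d_da &&
          th >= criteria$ch_min_theta
      } else {
        dha[w] <= criteria$nh_max_d_ha && d_da <= criteria$nh_max_d_da &&
          th >= criteria$nh_min_theta
      }
      if (!ok) next
      nr <- nr + 1
      if (nr > length(rows)) rows <- c(rows, vector("list", length(rows)))
      rows[[nr]] <- data.frame(
        donor_chain = a$chain[pi], donor_resno = a$resno[pi],
        donor_ins = a$ins[pi], donor_resname = a$resname[pi],
        donor_atom = a$atom[pi], h_atom = a$atom[hi],
        h_provenance = a$provenance[hi],
        acceptor_chain = a$chain[ai], acceptor_resno = a$resno[ai],
        acceptor_ins = a$ins[ai], acceptor_resname = a$resname[ai],
        acceptor_atom = a$atom[ai],
        d_HA = dha[w], d_DA = d_da, theta_DHA = th,
        bond_type = if (ch) "CH_O" else "NH_O",
        donor_class = if (a$atom[pi] %in% c("N", "CA") &&
                          a$class[pi] == "polymer") "main_chain" else "side_chain",
        acceptor_class = if (a$class[ai] == "solvent") "water"
          else if (a$class[ai] == "ligand") "ligand_O"
          else if (a$atom[ai] %in% c("O", "OXT")) "main_chain_carbonyl"
          else "side_chain_O",
        motif = NA_character_, stringsAsFactors = FALSE)
    }
  }
  if (nr == 0) return(empty_bonds())
  out <- do.call(rbind, rows[seq_len(nr)])
  out[order(out$donor_chain, out$donor_resno, out$donor_ins, out$donor_atom,
            out$acceptor_chain, out$acceptor_resno, out$acceptor_atom,
            out$d_HA), , drop = FALSE]
}

polymer_residue_index <- function(atoms) {
  # sequential index of polymer residues per chain (file order)
  pk <- residue_key(atoms)[atoms$class == "polymer"]
  keys <- pk[!duplicated(pk)]
  stats::setNames(seq_along(keys), keys)
}

backbone_bond_map <- function(bonds, res_index) {
  # (i, j) pairs: backbone N-H of residue i donates to backbone O of residue j
  bb <- bonds[bonds$bond_type == "NH_O" & bonds$donor_atom == "N" &
                bonds$acceptor_atom %in% c("O", "OXT"), , drop = FALSE]
  if (nrow(bb) == 0) return(data.frame(i = integer(), j = integer()))
  di <- res_index[paste(bb$donor_chain, bb$donor_resno, bb$donor_ins, sep = "|")]
  aj <- res_index[paste(bb$acceptor_chain, bb$acceptor_resno, bb$acceptor_ins,
                        sep = "|")]
  keep <- !is.na(di) & !is.na(aj)
  unique(data.frame(i = unname(di[keep]), j = unname(aj[keep])))
}

#' Assign secondary structure from backbone hydrogen-bond patterns
#'
#' DSSP-style minimal rules on backbone N-H...O=C bonds: `H` for residues
#' covered by two consecutive i -> i+4 bonds, `E` for residues in bridge
#' ladders (antiparallel or parallel, |i-j| >= 3 or cross-chain), `T` for
#' residues spanned by an i -> i+3 turn bond outside helices/strands, else
#' `C`. Priority H > E > T.
#'
#' @param model a `StructureModel`; hydrogens are placed automatically when
#'   absent (`keep_existing`).
#' @param bonds optional precomputed bond table from [find_hbonds()].
#' @param criteria criteria used when `bonds` is not supplied.
#' @return `SSAssignment`: data.frame (chain, resno, ins, resname, ss).
#' @export
assign_secondary_structure <- function(model, bonds = NULL,
                                       criteria = hbond_criteria()) {
  a <- model$atoms
  if (!any(is_hydrogen(a$element))) model <- place_hydrogens(model)
  if (is.null(bonds)) bonds <- find_hbonds(model, criteria)
  views <- residue_views(model, class = "polymer")
  n <- length(views)
  res_index <- polymer_residue_index(model$atoms)
  ss <- rep("C", n)
  chains <- vapply(views, `[[`, character(1), "chain")
  if (n >= 3) {
    hb <- backbone_bond_map(bonds, res_index)
    has <- function(i, j) any(hb$i == i & hb$j == j)
    same_chain <- function(i, j) chains[i] == chains[j]
    # helices: two consecutive i -> i+4 turns
    turn4 <- vapply(seq_len(max(n - 4, 0)), function(i) {
      has(i + 4, i) && same_chain(i, i + 4)
    }, logical(1))
    for (i in seq_len(max(n - 5, 0))) {
      if (turn4[i] && turn4[i + 1]) ss[(i + 1):(i + 4)] <- "H"
    }
    # strands: DSSP bridge definitions
    bridge <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        if (same_chain(i, j) && abs(i - j) < 3) next
        anti <- (has(i, j) && has(j, i)) ||
          (i > 1 && j < n && i < n && j > 1 &&
             has(i - 1, j + 1) && has(j - 1, i + 1))
        para <- (i > 1 && i < n && has(j, i - 1) && has(i + 1, j)) ||
          (j > 1 && j < n && has(i, j - 1) && has(j + 1, i))
        if (anti || para) bridge[i, j] <- TRUE
      }
    }
    for (i in seq_len(n)) {
      if (ss[i] == "C" && any(bridge[i, ])) ss[i] <- "E"
    }
    # turns: i -> i+3 bond, remaining residues
    for (i in seq_len(max(n - 3, 0))) {
      if (has(i + 3, i) && same_chain(i, i + 3)) {
        sel <- i:(i + 3)
        ss[sel][ss[sel] == "C"] <- "T"
      }
    }
  }
  out <- data.frame(
    chain = chains,
    resno = vapply(views, `[[`, integer(1), "resno"),
    ins = vapply(views, `[[`, character(1), "ins"),
    resname = vapply(views, `[[`, character(1), "resname"),
    ss = ss, stringsAsFactors = FALSE)
  class(out) <- c("SSAssignment", class(out))
  out
}

helix_segments <- function(ss) {
  r <- rle(ss$ss == "H")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Classify side-chain C-H...O bonds into capping motifs
#'
#' Motifs (side-chain C-H donor to main-chain carbonyl acceptor at index i,
#' donor residue index j, same chain):
#' * `turn_i_i3_sc_cap`: j = i+3 and the backbone N-H(i+3) -> O(i) turn bond
#'   coexists outside a helix.
#' * `helix_sc_cap_i3` / `helix_sc_cap_i4`: acceptor inside a helix,
#'   j = i+3 / i+4 with the donor still within the helix.
#' * `helix_c_cap`: same offsets but the donor residue lies at or beyond the
#'   helix C-terminal end (capping the last turn).
#' * `sheet_sc_extension`: acceptor at (or adjacent to) a strand terminus
#'   and a sequence-distant or cross-chain donor.
#' Everything else (and every main-chain-donor bond) is `other`.
#'
#' @param bonds data.frame from [find_hbonds()].
#' @param ss `SSAssignment` from [assign_secondary_structure()] on the same
#'   model.
#' @return list: `bonds` (motif column filled), `summary` (count per motif),
#'   `turn_cap_fraction` (fraction of detected i -> i+3 turns that carry a
#'   side-chain cap).
#' @export
classify_motifs <- function(bonds, ss) {
  res_index <- stats::setNames(seq_len(nrow(ss)),
                               paste(ss$chain, ss$resno, ss$ins, sep = "|"))
  hb <- backbone_bond_map(bonds, res_index)
  has <- function(i, j) any(hb$i == i & hb$j == j)
  segs <- helix_segments(ss)
  in_helix <- function(i) any(segs$start <= i & segs$end >= i)
  helix_of <- function(i) segs[segs$start <= i & segs$end >= i, , drop = FALSE]
  e_run <- rle(ss$ss == "E")
  e_ends <- cumsum(e_run$lengths)
  e_starts <- e_ends - e_run$lengths + 1
  strand_termini <- c(e_starts[e_run$values], e_ends[e_run$values])

  motifs <- rep("other", nrow(bonds))
  turn_list <- hb[hb$i - hb$j == 3, , drop = FALSE]
  turns_capped <- logical(nrow(turn_list))

  for (k in seq_len(nrow(bonds))) {
    b <- bonds[k, ]
    if (b$bond_type != "CH_O" || b$donor_class != "side_chain" ||
        b$acceptor_class != "main_chain_carbonyl") next
    i <- res_index[paste(b$acceptor_chain, b$acceptor_resno, b$acceptor_ins,
                         sep = "|")]
    j <- res_index[paste(b$donor_chain, b$donor_resno, b$donor_ins, sep = "|")]
    if (is.na(i) || is.na(j)) next
    same_chain <- b$donor_chain == b$acceptor_chain
    off <- j - i
    if (same_chain && off == 3 && has(j, i) && !in_helix(i)) {
      motifs[k] <- "turn_i_i3_sc_cap"
      tm <- which(turn_list$j == i & turn_list$i == j)
      if (length(tm) > 0) turns_capped[tm] <- TRUE
      next
    }
    if (same_chain && off %in% c(3, 4) && in_helix(i)) {
      hseg <- helix_of(i)
      if (j > hseg$end[1]) {
        motifs[k] <- "helix_c_cap"
      } else {
        motifs[k] <- if (off == 3) "helix_sc_cap_i3" else "helix_sc_cap_i4"
      }
      next
    }
    near_strand_term <- length(strand_termini) > 0 &&
      any(abs(strand_termini - i) <= 1)
    if (near_strand_term && (!same_chain || abs(off) > 2)) {
      motifs[k] <- "sheet_sc_extension"
    }
  }
  bonds$motif <- motifs
  levels <- c("sheet_mc_mc", "sheet_sc_extension", "turn_i_i3_sc_cap",
              "helix_sc_cap_i3", "helix_sc_cap_i4", "helix_c_cap", "other")
  summary <- data.frame(motif = levels,
                        count = vapply(levels, function(l) sum(motifs == l),
                                       integer(1)),
                        row.names = NULL, stringsAsFactors = FALSE)
  frac <- if (nrow(turn_list) > 0) mean(turns_capped) else NA_real_
  list(bonds = bonds, summary = summary, turn_cap_fraction = frac)
}
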