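# Eigen-analysis of anisotropic displacement tensors. Anisotropy is the
# PARVATI-style ratio lambda_min / lambda_max (1 = isotropic sphere, -> 0 =
# extreme elongation); this convention is stated explicitly because
# "anisotropy" has competing definitions in the literature.

atom_u_matrix <- function(atom) {
  matrix(c(atom$u11, atom$u12, atom$u13,
           atom$u12, atom$u22, atom$u23,
           atom$u13, atom$u23, atom$u33), 3, 3)
}

#' Eigen-structure and anisotropy of one atom's displacement tensor
#'
#' @param atom single-row atom data.frame with uij columns set.
#' @return an `AnisoTensor`: list with `U` (3x3), `eigenvalues` (decreasing),
#'   `eigenvectors` (columns, orthonormal), `anisotropy` (lambda_min /
#'   lambda_max), `b_eq` and `valid` (`FALSE` for a non-positive-definite
#'   tensor, which is excluded from group statistics).
#' @export
atom_anisotropy <- function(atom) {
  if (is.na(atom$u11)) stop("atom carries no uij tensor", call. = FALSE)
  U <- atom_u_matrix(atom)
  e <- eigen(U, symmetric = TRUE)
  lam <- e$values              # decreasing
  valid <- lam[3] > 0
  structure(list(
    U = U, eigenvalues = lam, eigenvectors = e$vectors,
    anisotropy = if (valid) lam[3] / lam[1] else NA_real_,
    b_eq = (8 * pi^2 / 3) * sum(lam), valid = valid),
    class = "AnisoTensor")
}

#' @export
print.AnisoTensor <- function(x, ...) {
  cat(sprintf("AnisoTensor: anisotropy %.3f, B_eq %.2f A^2, eigenvalues %s%s\n",
              x$anisotropy, x$b_eq,
              paste(sprintf("%.4f", x$eigenvalues), collapse = "/"),
              if (x$valid) "" else " [not positive definite]"))
  invisible(x)
}

group_of <- function(class) {
  c(polymer = "protein", ligand = "ligand", solvent = "solvent")[class]
}

#' Per-group anisotropy statistics
#'
#' Arithmetic mean and population standard deviation (divisor N; switchable)
#' of the per-atom anisotropy ratio, for protein / ligand / solvent atoms.
#' Hydrogen/deuterium atoms and non-positive-definite tensors are excluded by
#' default; both exclusions are counted in the output.
#'
#' @param model a `StructureModel` with uij on at least one atom.
#' @param exclude_hydrogen drop H/D atoms (default `TRUE`).
#' @param sample_sd use the sample (divisor N-1) standard deviation instead
#'   of the population one.
#' @return data.frame: group, n (atoms used), n_invalid (NPD tensors),
#'   mean_anisotropy, sd_anisotropy. Groups with no valid tensor are absent.
#' @export
group_anisotropy <- function(model, exclude_hydrogen = TRUE,
                             sample_sd = FALSE) {
  a <- model$atoms
  if (exclude_hydrogen) a <- a[!is_hydrogen(a$element), , drop = FALSE]
  a <- a[!is.na(a$u11), , drop = FALSE]
  if (nrow(a) == 0) {
    return(data.frame(group = character(), n = integer(),
                      n_invalid = integer(), mean_anisotropy = numeric(),
                      sd_anisotropy = numeric(), stringsAsFactors = FALSE))
  }
  aniso <- vapply(seq_len(nrow(a)), function(i) {
    t <- atom_anisotropy(a[i, ])
    if (t$valid) t$anisotropy else NA_real_
  }, numeric(1))
  grp <- group_of(a$class)
  out <- lapply(unique(grp), function(g) {
    v <- aniso[grp == g]
    bad <- sum(is.na(v))
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NULL)
    sdv <- if (length(v) == 1) 0 else {
      if (sample_sd) stats::sd(v) else sqrt(mean((v - mean(v))^2))
    }
    data.frame(group = g, n = length(v), n_invalid = bad,
               mean_anisotropy = mean(v), sd_anisotropy = sdv,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Per-group mean isotropic B factor
#'
#' @param model a `StructureModel`.
#' @param exclude_hydrogen drop H/D atoms (default `TRUE`).
#' @return data.frame: group, n, mean_b. Empty groups are absent.
#' @export
group_b_factor <- function(model, exclude_hydrogen = TRUE) {
  a <- model$atoms
  if (exclude_hydrogen) a <- a[!is_hydrogen(a$element), , drop = FALSE]
  a <- a[!is.na(a$b), , drop = FALSE]
  if (nrow(a) == 0) {
    return(data.frame(group = character(), n = integer(), mean_b = numeric(),
                      stringsAsFactors = FALSE))
  }
  grp <- group_of(a$class)
  do.call(rbind, lapply(unique(grp), function(g) {
    data.frame(group = g, n = sum(grp == g), mean_b = mean(a$b[grp == g]),
               stringsAsFactors = FALSE)
  }))
}

#' Export per-residue principal displacement axes as a graphics script
#'
#' For each residue the largest-eigenvalue directions of its atoms' tensors
#' are sign-aligned (positive dot product with the outward radial vector from
#' the molecular centroid), averaged and renormalized. Atoms whose two
#' largest eigenvalues are nearly degenerate (ratio > 0.95) have no defined
#' axis and are skipped; residues with no usable atom are omitted and
#' counted. The output is a plain-text PyMOL CGO command script drawing one
#' segment per residue, length `scale` x mean largest eigenvalue.
#'
#' @param model a `StructureModel` with uij tensors.
#' @param scale segment length per unit eigenvalue, angstrom per angstrom^2.
#' @param path optional file to write; when `NULL` the script lines are
#'   returned.
#' @return character vector of script lines (invisibly when written);
#'   `attr(, "axes")` carries the numeric table (residue, direction, length),
#'   `attr(, "n_degenerate")` the omitted-residue count.
#' @export
export_axes <- function(model, scale = 20, path = NULL) {
  a <- model$atoms
  a <- a[!is.na(a$u11) & !is_hydrogen(a$element), , drop = FALSE]
  if (nrow(a) == 0) stop("no anisotropic tensors in model", call. = FALSE)
  centroid <- c(mean(a$x), mean(a$y), mean(a$z))
  key <- residue_key(a)
  segs <- list()
  n_degen <- 0
  for (kk in unique(key)) {
    sel <- a[key == kk, , drop = FALSE]
    dirs <- list(); lens <- numeric()
    rc <- c(mean(sel$x), mean(sel$y), mean(sel$z))
    radial <- rc - centroid
    if (vnorm(radial) < 1e-9) radial <- c(0, 0, 1)
    for (i in seq_len(nrow(sel))) {
      t <- atom_anisotropy(sel[i, ])
      if (!t$valid) next
      if (t$eigenvalues[2] / t$eigenvalues[1] > 0.95) next   # degenerate axis
      v <- t$eigenvectors[, 1]
      if (sum(v * radial) < 0) v <- -v
      dirs[[length(dirs) + 1]] <- v
      lens <- c(lens, t$eigenvalues[1])
    }
    if (length(dirs) == 0) {
      n_degen <- n_degen + 1
      next
    }
    m <- Reduce(`+`, dirs) / length(dirs)
    if (vnorm(m) < 1e-9) { n_degen <- n_degen + 1; next }
    m <- vunit(m)
    if (sum(m * radial) < 0) m <- -m
    segs[[length(segs) + 1]] <- data.frame(
      residue = kk, cx = rc[1], cy = rc[2], cz = rc[3],
      dx = m[1], dy = m[2], dz = m[3],
      length = scale * mean(lens), stringsAsFactors = FALSE)
  }
  axes <- if (length(segs) > 0) do.call(rbind, segs) else NULL
  lines <- c("from pymol.cgo import CYLINDER", "obj = []")
  if (!is.null(axes)) {
    half <- axes$length / 2
    lines <- c(lines, sprintf(
      "obj += [CYLINDER, %.3f, %.3f, %.3f, %.3f, %.3f, %.3f, 0.05, 1,0.5,0, 1,0.5,0]",
      axes$cx - half * axes$dx, axes$cy - half * axes$dy, axes$cz - half * axes$dz,
      axes$cx + half * axes$dx, axes$cy + half * axes$dy, axes$cz + half * axes$dz))
  }
  lines <- c(lines, sprintf("cmd.load_cgo(obj, 'adp_axes_%s')", model$entry_id))
  attr(lines, "axes") <- axes
  attr(lines, "n_degenerate") <- n_degen
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
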