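# Reading and writing pMHC structures, receptor/peptide splitting and
# peptide preparation.

.WATER_CODES <- c("HOH", "WAT", "DOD", "H2O")

#' Read a peptide--MHC complex from a PDB file
#'
#' Parses a PDB file (via bio3d), resolves alternate locations to the
#' highest-occupancy copy, discards waters, classifies chains into
#' receptor, peptide and hetero groups, and annotates the MHC class and
#' the groove region. The peptide chain is auto-detected as the shortest
#' polymer chain with 6--25 residues unless `peptide_chain` is given.
#'
#' @param path PDB file path.
#' @param peptide_chain Optional chain identifier overriding peptide
#'   auto-detection.
#' @param mhc_class Optional "I" or "II"; inferred from peptide length
#'   (<= 11 residues implies class I) when absent.
#' @param allele Free-text allele label carried through to reports.
#' @return An object of class `pmhc`: the atom table plus `receptor_idx`,
#'   `peptide_idx`, `hetero` (list of atom index vectors per hetero
#'   group), `mhc_class`, `allele` and a logical `groove` flag marking
#'   receptor atoms lining the binding groove.
#' @export
read_pmhc <- function(path, peptide_chain = NULL, mhc_class = NULL,
                      allele = NA_character_) {
  .check_pdb_lines(path)
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[!(at$resid %in% .WATER_CODES), , drop = FALSE]
  at <- .resolve_altloc(at)
  atoms <- data.frame(
    type = at$type, elety = at$elety, resid = at$resid, chain = at$chain,
    resno = at$resno, x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o), stringsAsFactors = FALSE)
  atoms$is_hetero <- atoms$type == "HETATM"
  .classify_complex(atoms, peptide_chain = peptide_chain,
                    mhc_class = mhc_class, allele = allele, path = path)
}

.check_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM|HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop(sprintf("malformed PDB record at line %d of %s: truncated", i,
                   path))
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz))
      stop(sprintf("malformed PDB record at line %d of %s: bad coordinates",
                   i, path))
  }
  invisible(TRUE)
}

.resolve_altloc <- function(at) {
  alt <- at$alt
  if (all(is.na(alt) | alt == "")) return(at)
  keykeep <- paste(at$chain, at$resno, at$elety)
  keep <- rep(TRUE, nrow(at))
  for (k in unique(keykeep[!is.na(alt) & alt != ""])) {
    w <- which(keykeep == k)
    if (length(w) > 1) {
      occ <- ifelse(is.na(at$o[w]), 0, at$o[w])
      best <- w[order(-occ, at$alt[w])[1]]
      keep[setdiff(w, best)] <- FALSE
    }
  }
  at[keep, , drop = FALSE]
}

.classify_complex <- function(atoms, peptide_chain = NULL, mhc_class = NULL,
                              allele = NA_character_, path = NULL,
                              resolution = NA_real_) {
  poly <- !atoms$is_hetero
  chains <- unique(atoms$chain[poly])
  # polymer chains need backbone atoms in >= 2 residues
  is_poly <- vapply(chains, function(ch) {
    a <- atoms[atoms$chain == ch & poly, ]
    res <- split(a$elety, a$resno)
    sum(vapply(res, function(n) all(c("N", "CA", "C") %in% n), TRUE)) >= 2
  }, TRUE)
  pchains <- chains[is_poly]
  if (length(pchains) < 2)
    stop("classification error: need at least two polymer chains")
  nres <- vapply(pchains, function(ch)
    length(unique(atoms$resno[atoms$chain == ch & poly])), 1L)
  if (!is.null(peptide_chain)) {
    if (!peptide_chain %in% pchains)
      stop("classification error: no polymer chain ", peptide_chain)
    pep_chain <- peptide_chain
  } else {
    cand <- pchains[nres >= 6 & nres <= 25]
    if (!length(cand))
      stop("classification error: no candidate peptide chain ",
           "(6-25 residues); use peptide_chain to override")
    pep_chain <- cand[which.min(nres[match(cand, pchains)])]
  }
  peptide_idx <- which(atoms$chain == pep_chain & poly)
  receptor_idx <- which(atoms$chain != pep_chain & poly)
  het <- which(atoms$is_hetero)
  hetero <- if (length(het)) {
    split(het, paste(atoms$chain[het], atoms$resno[het], atoms$resid[het]))
  } else list()
  pep_len <- length(unique(atoms$resno[peptide_idx]))
  if (is.null(mhc_class)) mhc_class <- if (pep_len <= 11) "I" else "II"
  # groove flag: receptor atoms within 8.5 A of any peptide atom
  groove <- rep(FALSE, nrow(atoms))
  rxyz <- as.matrix(atoms[receptor_idx, c("x", "y", "z")])
  pxyz <- as.matrix(atoms[peptide_idx, c("x", "y", "z")])
  near <- vapply(seq_len(nrow(rxyz)), function(i)
    min(sqrt(colSums((t(pxyz) - rxyz[i, ])^2))) <= 8.5, TRUE)
  groove[receptor_idx[near]] <- TRUE
  structure(list(
    atoms = atoms, receptor_idx = receptor_idx, peptide_idx = peptide_idx,
    peptide_chain = pep_chain, hetero = hetero, mhc_class = mhc_class,
    allele = allele, resolution = resolution, groove = groove,
    path = path), class = "pmhc")
}

#' @export
print.pmhc <- function(x, ...) {
  cat(sprintf("pmhc complex: MHC class %s, peptide chain %s (%d residues),",
              x$mhc_class, x$peptide_chain,
              length(unique(x$atoms$resno[x$peptide_idx]))),
      sprintf("%d receptor atoms, %d hetero group(s)\n",
              length(x$receptor_idx), length(x$hetero)))
  invisible(x)
}

#' Split a complex into receptor atoms and a flexible ligand
#'
#' The peptide chain is extracted into the internal-coordinate
#' `peptide_conformation` model (its torsions measured from the crystal
#' coordinates, its Cartesian coordinates an exact copy of them); the
#' remaining polymer atoms form the receptor set. Hetero groups (e.g. a
#' bound formic acid molecule) are excluded from the receptor unless
#' `include_hetero` is set, in which case their atoms are appended to the
#' receptor side.
#'
#' @param cx A `pmhc` complex.
#' @param include_hetero Include non-water hetero groups as receptor atoms.
#' @return list with `receptor` (atom data.frame), `ligand`
#'   (`peptide_conformation` carrying the crystal coordinates and a
#'   `reference_ca` attribute) and `n_skipped_hetero`.
#' @export
split_complex <- function(cx, include_hetero = FALSE) {
  stopifnot(inherits(cx, "pmhc"))
  rec <- cx$atoms[cx$receptor_idx, , drop = FALSE]
  rec$groove <- cx$groove[cx$receptor_idx]
  n_het <- 0L
  if (include_hetero && length(cx$hetero)) {
    hidx <- unlist(cx$hetero, use.names = FALSE)
    h <- cx$atoms[hidx, , drop = FALSE]
    h$groove <- FALSE
    rec <- rbind(rec, h)
  } else {
    n_het <- length(unlist(cx$hetero, use.names = FALSE))
  }
  pep <- cx$atoms[cx$peptide_idx, , drop = FALSE]
  lig <- .conformation_from_atoms(pep)
  list(receptor = rec, ligand = lig, n_skipped_hetero = n_het)
}

# Build a peptide_conformation from crystal peptide atoms: measure the
# torsions, fit the rigid-body placement, then overwrite matched atom
# coordinates with the crystal copy.
.conformation_from_atoms <- function(pep) {
  resnos <- sort(unique(pep$resno))
  codes <- vapply(resnos, function(r) pep$resid[pep$resno == r][1], "")
  p <- peptide_conformation(codes)
  n <- nrow(p$atoms)
  match_idx <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    r <- resnos[p$atoms$residue_index[i]]
    w <- which(pep$resno == r & pep$elety == p$atoms$name[i])
    if (length(w)) match_idx[i] <- w[1]
  }
  have <- !is.na(match_idx)
  xyz <- matrix(NA_real_, n, 3)
  xyz[have, ] <- as.matrix(pep[match_idx[have], c("x", "y", "z")])
  p$torsions <- measure_torsions_partial(p, xyz)
  p <- rebuild_coords(p)
  # rigid fit of the idealized build onto the crystal (common atoms)
  fit <- .kabsch(p$coords[have, , drop = FALSE], xyz[have, , drop = FALSE])
  p$rotation <- fit$R %*% p$rotation
  p$translation <- as.numeric(fit$R %*% p$translation + fit$t)
  p <- rebuild_coords(p)
  # extraction is a copy: matched atoms keep crystal coordinates
  p$coords[have, ] <- xyz[have, ]
  attr(p, "reference_ca") <- p$coords[p$ca_idx, , drop = FALSE]
  attr(p, "crystal_match") <- have
  p
}

# torsion measurement tolerant to missing atoms
measure_torsions_partial <- function(p, xyz) {
  ok <- stats::complete.cases(xyz)
  safe <- xyz
  safe[!ok, ] <- 0
  tor <- tryCatch(measure_torsions(p, safe), error = function(e) p$torsions)
  tor
}

.kabsch <- function(A, B) {
  # rigid transform R, t minimizing |R A + t - B|; A, B are n x 3
  ca <- colMeans(A); cb <- colMeans(B)
  H <- t(sweep(A, 2, ca)) %*% sweep(B, 2, cb)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t <- cb - as.numeric(R %*% ca)
  list(R = R, t = t)
}

#' Randomize a peptide to an extended conformation
#'
#' Sets the backbone to antiparallel-beta extended values (phi = -139,
#' psi = +135, omega = 180 degrees), draws the side-chain chi angles
#' uniformly from (-180, 180] and, when a docking box is supplied, places
#' the peptide with a random rigid-body rotation and a random translation
#' inside the central half of the box. Fully deterministic for a given
#' seed.
#'
#' @param p A `peptide_conformation`.
#' @param seed Integer RNG seed.
#' @param box Optional `docking_box` used to randomize the placement.
#' @return The randomized, rebuilt conformation.
#' @export
set_extended_conformation <- function(p, seed = 1, box = NULL) {
  set.seed(seed)
  tor <- p$torsions
  tor[p$torsion_kind == "phi"] <- -139
  tor[p$torsion_kind == "psi"] <- 135
  tor[p$torsion_kind == "omega"] <- 180
  chi <- grepl("^chi", p$torsion_kind)
  rot_ok <- chi & !(p$parent_codes[p$torsion_res] == "PRO")
  tor[rot_ok] <- stats::runif(sum(rot_ok), -180, 180)
  p$torsions <- tor
  if (!is.null(box)) {
    qn <- stats::rnorm(4)
    qn <- qn / sqrt(sum(qn^2))
    p$rotation <- .quat_to_mat(qn)
    p <- rebuild_coords(p)
    cen <- colMeans(p$coords)
    target <- box$center + stats::runif(3, -0.25, 0.25) * box$dims
    p$translation <- p$translation + (target - cen)
  }
  rebuild_coords(p)
}

.quat_to_mat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

#' Extract the nonameric core window
#'
#' Returns the residue window scored against the groove: the 9 residues
#' starting at the register for peptides longer than 9 residues, or the
#' whole peptide when it has 9 or fewer residues.
#'
#' @param p A `peptide_conformation`.
#' @param register A register assignment (1-based core start) or integer.
#' @return list with `residues` (indices), `atom_idx` (rows of `p$atoms`)
#'   and `whole_peptide` flag.
#' @export
extract_core <- function(p, register = 1L) {
  start <- if (is.list(register)) register$start else as.integer(register)
  n <- p$nres
  if (n <= 9L) {
    return(list(residues = seq_len(n), whole_peptide = TRUE,
                atom_idx = seq_len(nrow(p$atoms))))
  }
  if (start < 1L || start + 8L > n)
    stop("register window [", start, ", ", start + 8L,
         "] exceeds peptide length ", n)
  res <- start:(start + 8L)
  list(residues = res, whole_peptide = FALSE,
       atom_idx = which(p$atoms$residue_index %in% res))
}

# --- PDB writing -----------------------------------------------------------

.pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                           occ = 1, b = 0, hetero = FALSE) {
  rec <- if (hetero) "HETATM" else "ATOM  "
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  el <- substr(gsub("[0-9]", "", name), 1, 1)
  sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, nm, resid, chain, resno, x, y, z, occ, b, el)
}

.atoms_to_pdb_lines <- function(atoms, serial0 = 0L) {
  n <- nrow(atoms)
  vapply(seq_len(n), function(i)
    .pdb_atom_line(serial0 + i, atoms$elety[i], atoms$resid[i],
                   atoms$chain[i], atoms$resno[i], atoms$x[i], atoms$y[i],
                   atoms$z[i], atoms$o[i],
                   0, isTRUE(atoms$is_hetero[i])), "")
}

#' Write a complex or atom table to a PDB file
#'
#' @param x A `pmhc` complex or an atom data.frame with columns
#'   `elety, resid, chain, resno, x, y, z` (optional `o`, `is_hetero`).
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_pdb_file <- function(x, path) {
  atoms <- if (inherits(x, "pmhc")) x$atoms else x
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$is_hetero)) atoms$is_hetero <- FALSE
  lines <- c(.atoms_to_pdb_lines(atoms), "END")
  writeLines(lines, path)
  invisible(path)
}

#' Write docked poses as a multi-MODEL PDB
#'
#' @param poses A list of `peptide_conformation` objects (or one).
#' @param path Output file.
#' @param chain Chain identifier for the peptide.
#' @return Invisibly, the path.
#' @export
write_poses <- function(poses, path, chain = "P") {
  if (inherits(poses, "peptide_conformation")) poses <- list(poses)
  out <- character(0)
  for (m in seq_along(poses)) {
    p <- poses[[m]]
    atoms <- data.frame(
      elety = p$atoms$name, resid = p$codes[p$atoms$residue_index],
      chain = chain, resno = p$atoms$residue_index,
      x = p$coords[, 1], y = p$coords[, 2], z = p$coords[, 3],
      o = 1, is_hetero = FALSE, stringsAsFactors = FALSE)
    out <- c(out, sprintf("MODEL     %4d", m),
             .atoms_to_pdb_lines(atoms), "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Assemble a `pmhc` complex from an atom table
#'
#' Used by the synthetic fixture generator and anywhere a complex is built
#' in memory rather than read from disk.
#'
#' @param atoms Atom data.frame (`elety, resid, chain, resno, x, y, z`).
#' @param peptide_chain,mhc_class,allele See [read_pmhc()].
#' @return A `pmhc` object.
#' @export
as_pmhc <- function(atoms, peptide_chain = NULL, mhc_class = NULL,
                    allele = NA_character_) {
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$is_hetero)) atoms$is_hetero <- FALSE
  if (is.null(atoms$type)) atoms$type <- ifelse(atoms$is_hetero, "HETATM",
                                                "ATOM")
  .classify_complex(atoms, peptide_chain = peptide_chain,
                    mhc_class = mhc_class, allele = allele)
}
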