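# Interface refinement, C-alpha RMSD, register detection, correctness
# classification and dataset non-redundancy filtering.

# descendants of each side-chain atom in the residue bond tree, used to
# define which atoms a chi rotation moves
.side_tree <- function(code) {
  sc <- .SIDE_TEMPLATES[[code]]
  if (is.null(sc)) return(NULL)
  parent <- stats::setNames(sc$i, sc$name)
  parent["CB"] <- "CA"
  parent
}

.distal_atoms <- function(code, pivot) {
  parent <- .side_tree(code)
  if (is.null(parent)) return(character(0))
  out <- character(0)
  for (a in names(parent)) {
    p <- a
    repeat {
      p <- parent[[p]] %||% NA_character_
      if (is.na(p)) break
      if (p == pivot) { out <- c(out, a); break }
      if (!p %in% names(parent)) break
    }
  }
  out
}

# chi axes of a residue: list of (axis_from, axis_to, moving atom names)
.receptor_chi_axes <- function(code) {
  chain <- .chi_chain(code)
  if (length(chain) < 4) return(list())
  axes <- list()
  for (k in seq_len(length(chain) - 3)) {
    from <- chain[k + 1]; to <- chain[k + 2]
    axes[[k]] <- list(from = from, to = to,
                      moving = .distal_atoms(code, to))
  }
  Filter(function(a) length(a$moving) > 0, axes)
}

#' Refine the peptide--MHC interface
#'
#' Minimizes the refinement score over the mobile set: all ligand
#' torsions plus the rigid-body placement, and the side-chain chi angles
#' of receptor residues having atoms within `radius` (default 4.00 A) of
#' the ligand. Receptor atoms outside the mobile set are returned
#' bit-identical. Harmonic restraints keep the ligand C-alpha atoms near
#' their starting positions. Optimization is a deterministic cyclic
#' coordinate descent, so the refined score never exceeds the input
#' score.
#'
#' @param receptor Receptor atom data.frame (from [split_complex()]).
#' @param pose Docked `peptide_conformation`.
#' @param radius Mobility radius around the ligand (Angstrom).
#' @param ff Force field.
#' @param restraint_k C-alpha restraint constant (kcal/(mol A^2)).
#' @param sweeps Coordinate-descent sweeps over the variable set.
#' @param sasa_points SASA sampling density during refinement.
#' @return list with `receptor` (updated atoms), `pose` (refined
#'   conformation), `score_before`, `score_after`, `breakdown`
#'   (refinement terms of the final interface subsystem) and
#'   `mobile_receptor` (row indices of mobile receptor atoms).
#' @export
refine_interface <- function(receptor, pose, radius = 4.00,
                             ff = default_forcefield(), restraint_k = 1.0,
                             sweeps = 2, sasa_points = 240) {
  rxyz <- as.matrix(receptor[, c("x", "y", "z")])
  lxyz <- pose$coords
  # minimum distance from each receptor atom to the ligand
  mind <- .min_cross_dist(rxyz, lxyz)
  near_res <- unique(paste(receptor$chain, receptor$resno)[mind <= radius])
  res_key <- paste(receptor$chain, receptor$resno)
  mobile_res <- near_res
  # interface subsystem: receptor atoms within radius + nonbonded cutoff
  sub_idx <- which(mind <= radius + ff$nb_cutoff)
  # make sure whole residues enter the subsystem
  sub_idx <- which(res_key %in% unique(res_key[sub_idx]))
  sub <- receptor[sub_idx, , drop = FALSE]
  sub_key <- paste(sub$chain, sub$resno)
  rset <- .atoms_df_to_set(sub, ff)
  nl <- nrow(pose$atoms); nr <- nrow(sub)
  ctxl <- dock_context(NULL, pose, ff)
  # combined exclusions: ligand bonded; receptor same/adjacent residues
  excl <- matrix(FALSE, nl + nr, nl + nr)
  excl[seq_len(nl), seq_len(nl)] <- ctxl$excl
  # receptor-receptor pairs enter the score only when at least one side
  # is mobile: fixed-fixed contacts are constant and would only blur the
  # reported interface energy
  same_chain <- outer(sub$chain, sub$chain, "==")
  adj <- abs(outer(sub$resno, sub$resno, "-")) <= 1
  mobile_res_mask <- sub_key %in% near_res
  fixed_pair <- outer(!mobile_res_mask, !mobile_res_mask, "&")
  excl[nl + seq_len(nr), nl + seq_len(nr)] <- (same_chain & adj) |
    fixed_pair
  cls <- c(ctxl$cls, rset$cls)
  q <- c(ctxl$charge, rset$charge)
  don <- c(ctxl$donor, as.integer(rset$donor))
  donp <- c(ctxl$donp, ifelse(rset$donp > 0, rset$donp + nl, 0L))
  acc <- c(ctxl$acceptor, as.integer(rset$acceptor))
  rad <- ff$r0[cls]
  sigma <- ff$sigma[cls]
  ffc <- .ff_cpp(ff)
  ca_ref <- pose$coords[pose$ca_idx, , drop = FALSE]
  side_idx <- which(ctxl$side_atoms)

  sub_xyz <- as.matrix(sub[, c("x", "y", "z")])
  eval_system <- function(lig, rec_xyz, detail = FALSE) {
    xyz <- rbind(lig$coords, rec_xyz)
    it <- intra_terms_cpp(xyz, cls, q, don, donp, acc, excl, ffc)
    ar <- sasa_cpp(xyz, rad, ff$sasa_probe, as.integer(sasa_points),
                   seq_len(nl + nr))
    E_solv <- sum(sigma * ar)
    E_en <- 0
    if (length(side_idx)) {
      free_a <- sasa_cpp(lig$coords, rad[seq_len(nl)], ff$sasa_probe,
                         as.integer(sasa_points), as.integer(side_idx))
      res <- ctxl$atom_res[side_idx]
      for (r in unique(res)) {
        w <- side_idx[res == r]
        fa <- sum(free_a[res == r]); ca <- sum(ar[w])
        bf <- if (fa > 1e-9) min(1, max(0, 1 - ca / fa)) else 0
        E_en <- E_en + ctxl$entropy_max[r] * bf
      }
    }
    b <- energy_breakdown(E_vw = it$vw, E_hb = it$hb,
                          E_tors = .torsion_energy(lig, ff),
                          E_elec = it$el, E_solv = E_solv, E_en = E_en)
    s <- refinement_score(b)
    b$total <- s
    if (detail) list(score = s, breakdown = b) else s
  }
  objective <- function(lig, rec_xyz) {
    eval_system(lig, rec_xyz) +
      restraint_k * sum((lig$coords[pose$ca_idx, , drop = FALSE] - ca_ref)^2)
  }

  score_before <- eval_system(pose, sub_xyz)
  cur_l <- pose
  cur_r <- sub_xyz
  cur_obj <- objective(cur_l, cur_r)

  # variable list: ligand torsions, 6 rigid dof, receptor chi rotations
  lig_vars <- c(ctxl$chi_idx, ctxl$bb_idx)
  rec_vars <- list()
  for (rk in mobile_res) {
    w <- which(sub_key == rk)
    if (!length(w)) next
    code <- sub$resid[w[1]]
    for (axis in .receptor_chi_axes(code)) {
      ia <- w[sub$elety[w] == axis$from]
      ib <- w[sub$elety[w] == axis$to]
      im <- w[sub$elety[w] %in% axis$moving]
      if (length(ia) == 1 && length(ib) == 1 && length(im))
        rec_vars[[length(rec_vars) + 1]] <- list(a = ia, b = ib, moving = im)
    }
  }

  for (sweep in seq_len(sweeps)) {
    improved <- FALSE
    for (tv in lig_vars) {  # ligand torsions, one at a time
      f <- function(v) {
        trial <- cur_l
        trial$torsions[tv] <- .wrap_angle(v)
        trial <- rebuild_coords(trial)
        objective(trial, cur_r)
      }
      v0 <- cur_l$torsions[tv]
      o <- stats::optimize(f, lower = v0 - 30, upper = v0 + 30)
      if (o$objective < cur_obj - 1e-9) {
        cur_l$torsions[tv] <- .wrap_angle(o$minimum)
        cur_l <- rebuild_coords(cur_l)
        cur_obj <- o$objective
        improved <- TRUE
      }
    }
    for (d in 1:6) {  # rigid-body line searches
      f <- function(v) {
        trial <- .apply_rigid_component(cur_l, d, v)
        objective(trial, cur_r)
      }
      lim <- if (d <= 3) 0.5 else 8
      o <- stats::optimize(f, lower = -lim, upper = lim)
      if (o$objective < cur_obj - 1e-9) {
        cur_l <- .apply_rigid_component(cur_l, d, o$minimum)
        cur_obj <- o$objective
        improved <- TRUE
      }
    }
    for (rv in rec_vars) {  # receptor side-chain rotations
      f <- function(v) {
        objective(cur_l, .rotate_subset(cur_r, rv$a, rv$b, rv$moving, v))
      }
      o <- stats::optimize(f, lower = -40, upper = 40)
      if (o$objective < cur_obj - 1e-9) {
        cur_r <- .rotate_subset(cur_r, rv$a, rv$b, rv$moving, o$minimum)
        cur_obj <- o$objective
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  fin <- eval_system(cur_l, cur_r, detail = TRUE)
  out_rec <- receptor
  out_rec[sub_idx, c("x", "y", "z")] <- cur_r
  list(receptor = out_rec, pose = cur_l, score_before = score_before,
       score_after = fin$score, breakdown = fin$breakdown,
       mobile_receptor = sub_idx[sub_key %in% mobile_res],
       subsystem = sub_idx)
}

.apply_rigid_component <- function(p, d, v) {
  cen <- colMeans(p$coords)
  if (d <= 3) {
    dt <- c(0, 0, 0); dt[d] <- v
    p$translation <- p$translation + dt
  } else {
    ax <- c(0, 0, 0); ax[d - 3] <- 1
    Rd <- .rot_axis(ax, v)
    p$rotation <- Rd %*% p$rotation
    p$translation <- as.numeric(Rd %*% (p$translation - cen)) + cen
  }
  rebuild_coords(p)
}

.rotate_subset <- function(xyz, ia, ib, moving, angle) {
  A <- xyz[ia, ]; B <- xyz[ib, ]
  ax <- B - A
  if (sum(ax^2) < 1e-12) return(xyz)
  Rd <- .rot_axis(ax, angle)
  out <- xyz
  out[moving, ] <- t(Rd %*% (t(xyz[moving, , drop = FALSE]) - B) + B)
  out
}

.min_cross_dist <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i)
    sqrt(min(colSums((t(b) - a[i, ])^2))), 1)
}

#' C-alpha RMSD over the scored core
#'
#' Root-mean-square deviation of C-alpha positions over the nonameric
#' core window (the whole peptide when it has 9 or fewer residues),
#' computed in the shared receptor frame with no superposition -- the
#' receptor stays fixed during docking, so pose and reference share a
#' frame. Set `superpose = TRUE` (with receptor C-alpha sets) for
#' cross-template comparisons.
#'
#' @param pose,reference `peptide_conformation` objects or n x 3 C-alpha
#'   coordinate matrices with matching residue order.
#' @param register Core start (1-based) used for peptides longer than 9.
#' @param superpose If TRUE, first superpose `fit_mobile` onto
#'   `fit_target` (Kabsch) and apply that transform to the pose.
#' @param fit_mobile,fit_target Optional receptor C-alpha matrices
#'   defining the superposition frame.
#' @return RMSD in Angstrom.
#' @export
ca_rmsd <- function(pose, reference, register = 1L, superpose = FALSE,
                    fit_mobile = NULL, fit_target = NULL) {
  A <- if (inherits(pose, "peptide_conformation"))
    pose$coords[pose$ca_idx, , drop = FALSE] else as.matrix(pose)
  B <- if (inherits(reference, "peptide_conformation"))
    reference$coords[reference$ca_idx, , drop = FALSE] else
      as.matrix(reference)
  if (nrow(A) != nrow(B))
    stop("pose and reference peptides have different lengths")
  n <- nrow(A)
  start <- if (is.list(register)) register$start else as.integer(register)
  win <- if (n <= 9L) seq_len(n) else {
    if (start < 1L || start + 8L > n)
      stop("register window exceeds peptide length")
    start:(start + 8L)
  }
  if (superpose) {
    if (is.null(fit_mobile) || is.null(fit_target))
      stop("superpose = TRUE needs fit_mobile and fit_target")
    fit <- .kabsch(as.matrix(fit_mobile), as.matrix(fit_target))
    A <- t(fit$R %*% t(A) + fit$t)
  }
  sqrt(mean(rowSums((A[win, , drop = FALSE] - B[win, , drop = FALSE])^2)))
}

#' Detect the binding register of a docked peptide
#'
#' Slides a 9-residue window along the peptide and returns the window
#' with the most heavy-atom contacts (pairs within the 4.50 A van der
#' Waals contact distance) to the binding-site atoms; ties go to the
#' smallest start. Peptides of 9 or fewer residues have register 1 and
#' are flagged whole-peptide.
#'
#' @param pose A docked `peptide_conformation`.
#' @param site A `binding_site` (carries the selected receptor atom
#'   coordinates).
#' @param contact_cutoff Contact distance (Angstrom).
#' @return list of class `register_assignment`: `start`,
#'   `whole_peptide`, `contacts` (per-window counts).
#' @export
detect_register <- function(pose, site, contact_cutoff = 4.50) {
  n <- pose$nres
  if (n <= 9L) {
    return(structure(list(start = 1L, whole_peptide = n < 9L,
                          contacts = NA_integer_),
                     class = "register_assignment"))
  }
  scoords <- site$coords
  counts <- integer(n - 8L)
  for (s in seq_len(n - 8L)) {
    w <- which(pose$atoms$residue_index %in% s:(s + 8L))
    counts[s] <- contact_count_cpp(pose$coords[w, , drop = FALSE], scoords,
                                   contact_cutoff)
  }
  structure(list(start = which.max(counts), whole_peptide = FALSE,
                 contacts = counts), class = "register_assignment")
}

#' Classify a docked pose as correct
#'
#' A docked peptide is correct when its core C-alpha RMSD from the
#' experimental pose is at most the threshold (2.50 A by default,
#' inclusive).
#'
#' @param rmsd RMSD in Angstrom (non-negative).
#' @param threshold Correctness bound (Angstrom).
#' @return logical.
#' @export
classify_correct <- function(rmsd, threshold = 2.50) {
  if (any(rmsd < 0)) stop("rmsd must be non-negative")
  rmsd <= threshold
}

#' Filter a structure dataset to non-redundant entries
#'
#' Groups peptide--MHC entries by (peptide, allele) -- and additionally by
#' T-cell receptor type for TR/pMHC entries -- and keeps the structure
#' with the best (numerically smallest) resolution per group, breaking
#' ties by PDB identifier.
#'
#' @param entries data.frame with columns `pdb_id`, `peptide`, `allele`,
#'   `resolution` and optional `tr_type`.
#' @return The filtered data.frame (original row order of kept entries).
#' @export
select_nonredundant <- function(entries) {
  stopifnot(all(c("pdb_id", "peptide", "allele", "resolution") %in%
                  names(entries)))
  tr <- if ("tr_type" %in% names(entries)) {
    ifelse(is.na(entries$tr_type), "", entries$tr_type)
  } else rep("", nrow(entries))
  key <- paste(entries$peptide, entries$allele, tr, sep = "\r")
  keep <- logical(nrow(entries))
  for (k in unique(key)) {
    w <- which(key == k)
    best <- w[order(entries$resolution[w], entries$pdb_id[w])[1]]
    keep[best] <- TRUE
  }
  entries[keep, , drop = FALSE]
}
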