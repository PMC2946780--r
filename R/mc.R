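# Biased Monte Carlo docking in the grid: probe placement, torsion and
# rigid-body moves, local minimization and Metropolis acceptance at 300 K.

#' Monte Carlo sampling parameters
#'
#' @param temperature_K Simulation temperature (default 300 K).
#' @param n_steps Maximum Monte Carlo steps.
#' @param patience Early stop after this many steps without improvement of
#'   the best score.
#' @param seed Integer RNG seed; every random draw in a docking run flows
#'   from it.
#' @param move_mix Probabilities of the three move kinds (side-chain
#'   biased pick, backbone pivot, rigid-body pseudo-Brownian); must sum
#'   to 1.
#' @param max_torsion Maximum torsion perturbation per move (degrees).
#' @param max_translation,max_rotation Rigid-body step bounds (Angstrom,
#'   degrees).
#' @param restraint_k Harmonic constant (kcal/(mol A^2)) of the loose
#'   positional restraint tying ligand C-alpha atoms to the current
#'   accepted pose.
#' @param restraint_k_torsion Harmonic constant (kcal/(mol deg^2)) of the
#'   loose restraint keeping backbone phi/psi near their values in the
#'   starting (extended) conformation, so the ligand stays close to the
#'   conformation it was started from.
#' @param anchor_k Harmonic constant (kcal/(mol A^2)) of the loose
#'   restraint keeping the ligand centroid near the probe position, so
#'   sampling stays inside the groove.
#' @param minimizer_maxit Local-minimizer iterations per proposal.
#' @param init_orientations Rigid orientations screened (by grid score)
#'   when anchoring the ligand at the probe position.
#' @param anchor_to_probe Anchor the ligand centroid at the probe node
#'   before sampling (disable to continue from the pose as given).
#' @param direction Groove-axis orientation handling: "both" splits the
#'   step budget between the two directions, "axis+" or "axis-" spends
#'   the whole budget on one of them (drivers alternate directions
#'   across replicas).
#' @param replicas Number of independently seeded trajectories a driver
#'   may run (the best pose overall is reported).
#' @return list of class `mc_params`. `gas_constant` is fixed at
#'   1.98720425864083e-3 kcal/(mol K).
#' @export
mc_params <- function(temperature_K = 300, n_steps = 20000, patience = 5000,
                      seed = 1,
                      move_mix = c(side = 0.5, backbone = 0.3, rigid = 0.2),
                      max_torsion = 30, max_translation = 1.0,
                      max_rotation = 10, restraint_k = 0.1,
                      restraint_k_torsion = 0.003, anchor_k = 0.2,
                      minimizer_maxit = 25, init_orientations = 24,
                      anchor_to_probe = TRUE, direction = "both",
                      replicas = 1) {
  stopifnot(abs(sum(move_mix) - 1) < 1e-9, length(move_mix) == 3)
  structure(list(temperature_K = temperature_K,
                 gas_constant = 1.98720425864083e-3,
                 n_steps = n_steps, patience = patience, seed = seed,
                 move_mix = move_mix, max_torsion = max_torsion,
                 max_translation = max_translation,
                 max_rotation = max_rotation, restraint_k = restraint_k,
                 restraint_k_torsion = restraint_k_torsion,
                 anchor_k = anchor_k,
                 minimizer_maxit = minimizer_maxit,
                 init_orientations = init_orientations,
                 anchor_to_probe = anchor_to_probe, direction = direction,
                 replicas = replicas),
            class = "mc_params")
}

#' Metropolis acceptance
#'
#' Accepts with probability `min(1, exp(-dG / RT))`: every downhill or
#' neutral move (`dG <= 0`) is accepted, uphill moves with Boltzmann
#' probability at the configured temperature.
#'
#' @param dG Energy change (kcal/mol); must be finite.
#' @param params `mc_params`.
#' @return logical.
#' @export
metropolis_accept <- function(dG, params = mc_params()) {
  stopifnot(is.finite(dG))
  if (dG <= 0) return(TRUE)
  stats::runif(1) < exp(-dG / (params$gas_constant * params$temperature_K))
}

# --- ligand energy context -------------------------------------------------

# bond graph of the conformation: z-matrix tree edges plus ring closures
.ligand_bonds <- function(p) {
  n <- nrow(p$atoms)
  from <- integer(0); to <- integer(0)
  for (r in 2:n) {
    if (p$zmat$i[r] > 0) { from <- c(from, p$zmat$i[r]); to <- c(to, r) }
  }
  closures <- list(
    PRO = list(c("CD", "N")), PHE = list(c("CZ", "CE2")),
    TYR = list(c("CZ", "CE2")), HIS = list(c("CE1", "NE2")),
    TRP = list(c("NE1", "CE2"), c("CH2", "CZ3")))
  for (res in unique(p$atoms$residue_index)) {
    code <- p$parent_codes[res]
    for (cl in closures[[code]] %||% list()) {
      a <- which(p$atoms$residue_index == res & p$atoms$name == cl[1])
      b <- which(p$atoms$residue_index == res & p$atoms$name == cl[2])
      if (length(a) && length(b)) { from <- c(from, a); to <- c(to, b) }
    }
  }
  cbind(from, to)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# pairs separated by <= 3 bonds (1-2, 1-3, 1-4) are excluded
.exclusion_matrix <- function(p) {
  n <- nrow(p$atoms)
  bonds <- .ligand_bonds(p)
  adj <- vector("list", n)
  for (e in seq_len(nrow(bonds))) {
    a <- bonds[e, 1]; b <- bonds[e, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  excl <- matrix(FALSE, n, n)
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    frontier <- s
    for (d in 1:3) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.na(dist[nxt])]
      if (!length(nxt)) break
      dist[nxt] <- d
      frontier <- nxt
    }
    excl[s, !is.na(dist)] <- TRUE
  }
  diag(excl) <- TRUE
  excl
}

#' Build the docking energy context for a ligand
#'
#' Precomputes force-field typing, bonded exclusions and bookkeeping used
#' by every pose evaluation during a docking run.
#'
#' @param maps `grid_maps` (or NULL for grid-free evaluation against a
#'   receptor set stored separately).
#' @param ligand A `peptide_conformation` (template; its torsions may
#'   change during sampling).
#' @param ff Force field.
#' @return list of class `dock_context`.
#' @export
dock_context <- function(maps, ligand, ff = default_forcefield()) {
  ty <- type_atoms(ligand$atoms$code, ligand$atoms$name, ff)
  donp <- integer(nrow(ligand$atoms))
  for (i in which(ty$donor)) {
    w <- which(ligand$atoms$residue_index == ligand$atoms$residue_index[i] &
                 ligand$atoms$name == ty$donor_parent[i])
    if (length(w)) donp[i] <- w[1]
  }
  chi <- grepl("^chi", ligand$torsion_kind) &
    ligand$parent_codes[ligand$torsion_res] != "PRO"
  bb <- ligand$torsion_kind %in% c("phi", "psi") &
    !(ligand$torsion_kind == "phi" & ligand$torsion_res == 1)
  side_atoms <- !(ligand$atoms$name %in% c("N", "CA", "C", "O"))
  structure(list(
    maps = maps, ff = ff, ffc = .ff_cpp(ff),
    cls = ty$cls, charge = .add_terminal_charges(ligand, ty$charge),
    donor = as.integer(ty$donor),
    donp = as.integer(donp), acceptor = as.integer(ty$acceptor),
    apolar = as.integer(ty$apolar), excl = .exclusion_matrix(ligand),
    ca_idx = ligand$ca_idx, chi_idx = which(chi), bb_idx = which(bb),
    side_atoms = side_atoms,
    atom_res = ligand$atoms$residue_index,
    entropy_max = {
      s <- ff$entropy_max[ligand$parent_codes]
      s[is.na(s)] <- 0
      s
    },
    area_ref = 4 * pi * (ff$r0[ty$cls] + ff$sasa_probe)^2,
    sigma = ff$sigma[ty$cls],
    flat_channels = if (!is.null(maps)) .flatten_channels(maps),
    # averaging matrix: residues x side-chain atoms, for burial fractions
    res_avg = {
      side <- which(side_atoms)
      M <- matrix(0, ligand$nres, nrow(ligand$atoms))
      if (length(side)) {
        r <- ligand$atoms$residue_index[side]
        for (i in seq_along(side)) M[r[i], side[i]] <- 1
        cnt <- rowSums(M)
        M[cnt > 0, ] <- M[cnt > 0, , drop = FALSE] / cnt[cnt > 0]
      }
      M
    }), class = "dock_context")
}

#' Docking-stage energy of a pose
#'
#' Receptor--ligand terms come from the grid maps (trilinear
#' interpolation), intra-ligand van der Waals / electrostatic /
#' hydrogen-bond terms from the pairwise kernel with bonded exclusions,
#' and the solvation and side-chain entropy terms from a fast
#' burial-count estimate (the exact surface-based versions are applied at
#' refinement and in final reports). The total is the weighted docking
#' score.
#'
#' @param ctx A `dock_context`.
#' @param p A `peptide_conformation` (coords are rebuilt if stale).
#' @param weights Scoring weights.
#' @param rebuild Rebuild coordinates from internal coordinates first.
#' @return list with `score`, `breakdown` and `coords`.
#' @export
pose_energy <- function(ctx, p, weights = scoring_weights(),
                        rebuild = TRUE) {
  if (rebuild) p <- rebuild_coords(p)
  xyz <- p$coords
  intra <- intra_terms_cpp(xyz, ctx$cls, ctx$charge, ctx$donor, ctx$donp,
                           ctx$acceptor, ctx$excl, ctx$ffc)
  if (!is.null(ctx$maps)) {
    vals <- .interp_channels(ctx$maps, xyz, flat = ctx$flat_channels)
    lset <- list(charge = ctx$charge, donor = ctx$donor,
                 acceptor = ctx$acceptor, apolar = ctx$apolar)
    parts <- .combine_channels(vals[, 1:7, drop = FALSE], lset,
                               ctx$maps$out_of_box_penalty,
                               inside = vals[, 8])
  } else {
    parts <- list(E_vw = 0, E_el = 0, E_hb = 0, E_hp = 0,
                  burial = numeric(nrow(xyz)), n_outside = 0)
  }
  occl <- intra$nbr + parts$burial
  exposure <- pmin(1, pmax(0, 1 - occl / ctx$ff$burial_sat))
  E_solv <- sum(ctx$sigma * ctx$area_ref * exposure)
  bf <- pmin(1, occl / ctx$ff$burial_sat)
  E_en <- sum(ctx$entropy_max * as.numeric(ctx$res_avg %*% bf))
  b <- energy_breakdown(E_vw = intra$vw + parts$E_vw, E_en = E_en,
                        E_el = intra$el + parts$E_el,
                        E_hb = intra$hb + parts$E_hb, E_hp = parts$E_hp,
                        E_solv = E_solv)
  score <- docking_score(b, weights)
  b$total <- score
  list(score = score, breakdown = b, coords = xyz)
}

#' Place the probe in the groove
#'
#' Scans grid nodes in the central third of the box and returns the node
#' with the lowest steric field (attractive plus capped repulsive van der
#' Waals), ties broken by linear node index. The ligand centroid is
#' anchored there at the start of a docking run.
#'
#' @param maps `grid_maps`.
#' @param box Docking box (defaults to the box stored in the maps).
#' @param seed Unused; kept so drivers can thread one seed everywhere.
#' @return list with `pos` (3-vector) and `node` (array index).
#' @export
place_probe <- function(maps, box = maps$box, seed = NULL) {
  steric <- maps$channels$vdw_attractive + maps$channels$vdw_repulsive
  np <- maps$npts
  lo <- floor((np - 1) / 3) + 1
  hi <- ceiling(2 * (np - 1) / 3) + 1
  central <- array(FALSE, dim = np)
  central[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  cand <- which(central)
  best <- cand[which.min(steric[cand])]  # which.min takes first on ties
  ijk <- arrayInd(best, np)
  pos <- maps$origin + (as.numeric(ijk) - 1) * maps$spacing
  list(pos = pos, node = as.integer(ijk))
}

# --- moves -----------------------------------------------------------------

#' Propose a biased Monte Carlo move
#'
#' Draws a move kind from the configured mix: a biased side-chain pick
#' perturbing 1--3 chi angles, a backbone pivot perturbing 1--2 phi/psi
#' angles, or a rigid-body pseudo-Brownian step. Peptides without
#' rotatable side chains fall back to backbone moves. Unperturbed
#' torsions are left bit-identical.
#'
#' @param p A `peptide_conformation`.
#' @param params `mc_params`.
#' @param ctx Optional `dock_context`; when given together with
#'   `reference`, the proposal's `dG` (after local minimization, including
#'   the positional restraint) is computed.
#' @param reference Optional current accepted pose for the restraint.
#' @param start Optional starting conformation anchoring the backbone
#'   torsion restraint.
#' @return list of class `move_proposal`: `type`, `conf` (the proposed
#'   conformation), `tor_idx` (perturbed torsion indices), `rigid` flag
#'   and `dG` (NA unless `ctx` is supplied).
#' @export
propose_move <- function(p, params = mc_params(), ctx = NULL,
                         reference = NULL, start = NULL, anchor = NULL) {
  chi_ok <- which(grepl("^chi", p$torsion_kind) &
                    p$parent_codes[p$torsion_res] != "PRO")
  bb_ok <- which(p$torsion_kind %in% c("phi", "psi") &
                   !(p$torsion_kind == "phi" & p$torsion_res == 1))
  u <- stats::runif(1)
  mix <- cumsum(params$move_mix)
  type <- if (u < mix[1]) "side" else if (u < mix[2]) "backbone" else "rigid"
  if (type == "side" && !length(chi_ok)) type <- "backbone"
  q <- p
  tor_idx <- integer(0)
  rigid <- FALSE
  if (type == "side") {
    k <- sample(1:min(3, length(chi_ok)), 1)
    tor_idx <- sample(chi_ok, k)
    if (stats::runif(1) < 0.35) {
      # occasional full resample escapes locked rotamers that small
      # incremental steps cannot leave
      q$torsions[tor_idx] <- stats::runif(k, -180, 180)
    } else {
      q$torsions[tor_idx] <- .wrap_angle(
        q$torsions[tor_idx] +
          stats::runif(k, -params$max_torsion, params$max_torsion))
    }
  } else if (type == "backbone") {
    k <- sample(1:min(2, length(bb_ok)), 1)
    tor_idx <- sample(bb_ok, k)
    q$torsions[tor_idx] <- .wrap_angle(
      q$torsions[tor_idx] +
        stats::runif(k, -params$max_torsion, params$max_torsion))
  } else {
    rigid <- TRUE
    dt <- stats::runif(3, -params$max_translation, params$max_translation)
    ax <- stats::rnorm(3)
    ang <- stats::runif(1, -params$max_rotation, params$max_rotation)
    cen <- colMeans(q$coords)
    Rd <- .rot_axis(ax, ang)
    q$rotation <- Rd %*% q$rotation
    q$translation <- as.numeric(Rd %*% (q$translation - cen)) + cen + dt
  }
  q <- rebuild_coords(q)
  prop <- structure(list(type = type, conf = q, tor_idx = tor_idx,
                         rigid = rigid, dG = NA_real_),
                    class = "move_proposal")
  if (!is.null(ctx)) {
    ref <- if (is.null(reference)) p else reference
    obj <- .restrained_objective(ctx, ref, params, start = start,
                                 anchor = anchor)
    e0 <- obj(ref)
    mn <- local_minimize(q, obj, params,
                         vars = list(tor = tor_idx, rigid = rigid))
    prop$conf <- mn$conf
    prop$dG <- mn$value - e0
  }
  prop
}

.restrained_objective <- function(ctx, reference, params,
                                  weights = scoring_weights(),
                                  start = NULL, anchor = NULL) {
  ref_ca <- reference$coords[ctx$ca_idx, , drop = FALSE]
  k <- params$restraint_k
  ktor <- params$restraint_k_torsion %||% 0
  kanc <- params$anchor_k %||% 0
  start_bb <- if (!is.null(start)) start$torsions[ctx$bb_idx]
  function(p) {
    pe <- pose_energy(ctx, p, weights)
    pen <- k * sum((pe$coords[ctx$ca_idx, , drop = FALSE] - ref_ca)^2)
    if (!is.null(start_bb) && ktor > 0) {
      dv <- .wrap_angle(p$torsions[ctx$bb_idx] - start_bb)
      pen <- pen + ktor * sum(dv^2)
    }
    if (!is.null(anchor) && kanc > 0)
      pen <- pen + kanc * sum((colMeans(pe$coords) - anchor)^2)
    pe$score + pen
  }
}

# apply a parameter vector to the free variables of a conformation
.apply_pars <- function(p, vars, par) {
  nt <- length(vars$tor)
  if (nt) p$torsions[vars$tor] <- .wrap_angle(par[seq_len(nt)])
  if (isTRUE(vars$rigid)) {
    d <- par[nt + (1:6)]
    cen <- colMeans(p$coords)
    ang <- sqrt(sum(d[4:6]^2))
    Rd <- if (ang > 1e-9) .rot_axis(d[4:6] / ang, ang) else diag(3)
    p$rotation <- Rd %*% p$rotation
    p$translation <- as.numeric(Rd %*% (p$translation - cen)) + cen + d[1:3]
  }
  rebuild_coords(p)
}

#' Local minimization over a subset of pose variables
#'
#' Derivative-free (Nelder-Mead; Brent for one dimension) descent of the
#' supplied energy callable over the perturbed torsions and, optionally,
#' the six rigid-body degrees of freedom. The returned energy never
#' exceeds the input energy.
#'
#' @param p A `peptide_conformation` (the starting point).
#' @param energy A function taking a conformation and returning kcal/mol.
#' @param params `mc_params` (supplies the iteration budget).
#' @param vars list with `tor` (torsion indices) and `rigid` (logical).
#' @return list with `conf` (minimized conformation) and `value`.
#' @export
local_minimize <- function(p, energy, params = mc_params(),
                           vars = list(tor = integer(0), rigid = FALSE)) {
  e0 <- energy(p)
  if (!is.finite(e0)) stop("non-finite energy at minimization start")
  nt <- length(vars$tor)
  npar <- nt + if (isTRUE(vars$rigid)) 6L else 0L
  if (npar == 0L) return(list(conf = p, value = e0))
  par0 <- c(if (nt) p$torsions[vars$tor] else numeric(0),
            if (isTRUE(vars$rigid)) rep(0, 6) else numeric(0))
  fn <- function(par) energy(.apply_pars(p, vars, par))
  if (npar == 1L) {
    o <- stats::optimize(fn, lower = par0 - 20, upper = par0 + 20)
    if (o$objective < e0) {
      return(list(conf = .apply_pars(p, vars, o$minimum),
                  value = o$objective))
    }
    return(list(conf = p, value = e0))
  }
  o <- stats::optim(par0, fn, method = "Nelder-Mead",
                    control = list(maxit = params$minimizer_maxit))
  if (o$value < e0) {
    list(conf = .apply_pars(p, vars, o$par), value = o$value)
  } else {
    list(conf = p, value = e0)
  }
}

# Deterministic coordinate-descent relaxation of a pose in the docking
# score: rigid-body placement, side-chain chi angles and (optionally)
# small backbone adjustments. Used to optimize ligand starts before
# sampling and to settle fixture natives.
.pose_relax <- function(ctx, pep, sweeps = 2, bb_lim = 12,
                        rigid_lim = 0.8, weights = scoring_weights(),
                        ref_ca = NULL, ref_k = 0) {
  score <- function(p) {
    sc <- pose_energy(ctx, p)$score
    if (!is.null(ref_ca) && ref_k > 0)
      sc <- sc + ref_k * sum((p$coords[ctx$ca_idx, , drop = FALSE] -
                                ref_ca)^2)
    sc
  }
  cur <- rebuild_coords(pep)
  cur_s <- score(cur)
  for (sw in seq_len(sweeps)) {
    for (d in 1:6) {
      f <- function(v) score(.apply_rigid_component(cur, d, v))
      lim <- if (d <= 3) rigid_lim else 6
      o <- stats::optimize(f, lower = -lim, upper = lim)
      if (o$objective < cur_s - 1e-9) {
        cur <- .apply_rigid_component(cur, d, o$minimum)
        cur_s <- o$objective
      }
    }
    # joint rotamer scan per residue: escapes interlocked side-chain
    # states that one-angle line searches cannot leave
    res_chi <- split(ctx$chi_idx, ctx$atom_res[1] * 0 +
                       vapply(ctx$chi_idx, function(t)
                         as.integer(sub(".*_", "", names(pep$torsions)[t])),
                         1L))
    for (rc in res_chi) {
      x1 <- rc[1]
      x2 <- if (length(rc) > 1) rc[2] else NA
      grid1 <- seq(-150, 180, by = 60)
      grid2 <- if (!is.na(x2)) c(-90, 0, 90, 180) else 0
      # the vertical offset is scanned jointly with the rotamer: flips
      # of bulky side chains are often blocked unless the whole ligand
      # rises or sinks a little at the same time
      gridz <- if (rigid_lim > 0) c(-0.6, 0, 0.6) else 0
      best_v <- c(cur$torsions[x1], if (!is.na(x2)) cur$torsions[x2], 0)
      best_s2 <- cur_s
      for (v1 in grid1) for (v2 in grid2) for (dz in gridz) {
        q <- cur
        q$torsions[x1] <- v1
        if (!is.na(x2)) q$torsions[x2] <- v2
        q$translation[3] <- q$translation[3] + dz
        sc <- score(rebuild_coords(q))
        if (sc < best_s2 - 1e-9) {
          best_s2 <- sc
          best_v <- c(v1, if (!is.na(x2)) v2, dz)
        }
      }
      if (best_s2 < cur_s - 1e-9) {
        cur$torsions[x1] <- best_v[1]
        if (!is.na(x2)) cur$torsions[x2] <- best_v[2]
        cur$translation[3] <- cur$translation[3] + best_v[length(best_v)]
        cur <- rebuild_coords(cur)
        cur_s <- best_s2
      }
    }
    for (tv in c(ctx$chi_idx, if (bb_lim > 0) ctx$bb_idx)) {
      lim <- if (tv %in% ctx$bb_idx) bb_lim else 60
      f <- function(v) {
        q <- cur
        q$torsions[tv] <- .wrap_angle(v)
        score(rebuild_coords(q))
      }
      v0 <- cur$torsions[tv]
      o <- stats::optimize(f, lower = v0 - lim, upper = v0 + lim)
      if (o$objective < cur_s - 1e-9) {
        cur$torsions[tv] <- .wrap_angle(o$minimum)
        cur <- rebuild_coords(cur)
        cur_s <- o$objective
      }
    }
  }
  cur
}

#' Run biased Monte Carlo docking
#'
#' From an initialized ligand (typically a randomized extended
#' conformation), anchors the ligand centroid at the probe position,
#' screens a set of rigid orientations by grid score, then iterates
#' propose -> local minimize -> Metropolis accept at the configured
#' temperature. Loose harmonic restraints tie the ligand C-alpha atoms to
#' the current accepted pose. Fully deterministic for a given seed.
#'
#' @param maps `grid_maps` of the receptor.
#' @param ligand Starting `peptide_conformation`.
#' @param params `mc_params`.
#' @param ff Force field.
#' @param weights Scoring weights.
#' @return list of class `dock_trajectory`: `best` pose, `best_score`,
#'   `best_breakdown`, `final` pose, `accepted` (data.frame of accepted
#'   steps), `best_trace` (best-so-far score per step),
#'   `acceptance_count`, `steps_run`, `seed` and the parameter echo.
#' @export
run_docking <- function(maps, ligand, params = mc_params(),
                        ff = default_forcefield(),
                        weights = scoring_weights()) {
  set.seed(params$seed)
  ctx <- dock_context(maps, ligand, ff)
  cur <- ligand
  anchor_pos <- colMeans(cur$coords)
  if (isTRUE(params$anchor_to_probe %||% TRUE)) {
    pr <- place_probe(maps)
    cen <- colMeans(cur$coords)
    cur$translation <- cur$translation + (pr$pos - cen)
    cur <- rebuild_coords(cur)
    anchor_pos <- pr$pos
  }
  starts <- list(cur)
  if (params$init_orientations > 1) {
    # systematic screen: elongated peptides are aligned with the groove
    # axis in both directions over a fan of roll angles (plus random
    # orientations); the best start of each direction is kept and both
    # are burned in briefly, the better basin continuing to the full run
    anchor_pt <- colMeans(cur$coords)
    ax <- maps$groove_axis
    ca <- cur$coords[cur$ca_idx, , drop = FALSE]
    pv <- stats::prcomp(ca)$rotation[, 1]
    if (sum(pv * (ca[nrow(ca), ] - ca[1, ])) < 0) pv <- -pv
    mk <- function(Rc) {
      trial <- cur
      trial$rotation <- Rc %*% trial$rotation
      trial$translation <- as.numeric(Rc %*% (trial$translation -
                                                anchor_pt)) + anchor_pt
      rebuild_coords(trial)
    }
    starts <- list()
    if (!is.null(ax)) {
      # orientations are screened on a clean-side-chain copy (template
      # chi angles) so the randomized side chains cannot hide the
      # correct roll; the chosen orientation is then applied to the
      # actual randomized ligand
      clean <- cur
      tordef <- .default_torsions(list(
        torsion_names = cur$torsion_names, torsion_kind = cur$torsion_kind,
        torsion_res = cur$torsion_res, codes = cur$parent_codes))
      chi <- grepl("^chi", cur$torsion_kind)
      clean$torsions[chi] <- tordef[chi]
      clean <- rebuild_coords(clean)
      mk_clean <- function(Rc) {
        trial <- clean
        trial$rotation <- Rc %*% trial$rotation
        trial$translation <- as.numeric(Rc %*% (trial$translation -
                                                  anchor_pt)) + anchor_pt
        rebuild_coords(trial)
      }
      rolls <- if (params$n_steps >= 1500) seq(0, 315, by = 45) else
        seq(0, 270, by = 90)
      for (dir in list(ax, -ax)) {
        R0 <- .rotation_between(pv, dir)
        best_R <- NULL; best_e <- Inf
        for (roll in rolls) {
          Rc <- .rot_axis(dir, roll) %*% R0
          trial <- mk_clean(Rc)
          if (params$n_steps >= 1500)
            trial <- .pose_relax(ctx, trial, sweeps = 1, bb_lim = 0,
                                 rigid_lim = 1.5, weights = weights)
          e <- pose_energy(ctx, trial, weights, rebuild = FALSE)$score
          if (e < best_e) { best_e <- e; best_R <- Rc }
        }
        starts[[length(starts) + 1]] <- mk(best_R)
      }
    } else {
      cand <- list(diag(3))
      while (length(cand) < params$init_orientations) {
        qn <- stats::rnorm(4); qn <- qn / sqrt(sum(qn^2))
        cand[[length(cand) + 1]] <- .quat_to_mat(qn)
      }
      best_o <- NULL; best_e <- Inf
      for (Rc in cand) {
        trial <- mk(Rc)
        e <- pose_energy(ctx, trial, weights, rebuild = FALSE)$score
        if (e < best_e) { best_e <- e; best_o <- trial }
      }
      starts <- list(best_o)
    }
  }
  # pre-docking ligand optimization: resolve side-chain clashes of the
  # randomized extended start before sampling (skipped for zero-step
  # runs, which must return the initial pose untouched)
  if (params$n_steps > 0) {
    starts <- lapply(starts, function(s0) .pose_relax(ctx, s0, sweeps = 3,
                                                      bb_lim = 0,
                                                      rigid_lim = 2.5,
                                                      weights = weights))
  }
  polish <- function(p) .pose_relax(ctx, p, sweeps = 2, bb_lim = 10,
                                    rigid_lim = 1.0, weights = weights)
  # starts are polished over a fan of vertical offsets: entering a snug
  # groove is height-sensitive, and the descent cannot recover a start
  # pressed against the floor or the roof
  polish_zfan <- function(p) {
    best <- NULL; best_s <- Inf
    for (dz in c(-2, -1, 0, 1, 2)) {
      q <- p
      q$translation[3] <- q$translation[3] + dz
      q <- polish(rebuild_coords(q))
      sc <- pose_energy(ctx, q, weights, rebuild = FALSE)$score
      if (sc < best_s) { best_s <- sc; best <- q }
    }
    best
  }
  # heavy start polishing pays off only for production-size runs; short
  # exploratory runs use a single light polish
  use_heavy <- params$n_steps >= 1500
  start_polish <- if (use_heavy) polish_zfan else polish
  dirmode <- params$direction %||% "both"
  if (length(starts) > 1 && dirmode != "both") {
    starts <- starts[if (dirmode == "axis+") 1L else 2L]
  }
  if (length(starts) > 1) {
    # both groove directions are sampled with half the step budget each
    # (each from its fully polished start); the better trajectory is
    # reported. Direction can rarely be called from starting scores
    # alone, so both funnels are explored
    pol <- lapply(starts, start_polish)
    runs <- lapply(pol, function(p0)
      .mc_loop(ctx, p0, params, weights,
               n_steps = max(1L, params$n_steps %/% 2L),
               patience = max(1L, params$patience %/% 2L), start0 = p0,
               anchor = anchor_pos))
    pick <- which.min(vapply(runs, function(r) r$best_objective, 1))
    out <- runs[[pick]]
    out$steps_run <- sum(vapply(runs, function(r) r$steps_run, 1L))
    out$acceptance_count <- sum(vapply(runs,
                                       function(r) r$acceptance_count, 1L))
  } else {
    s0 <- if (params$n_steps > 0 && params$init_orientations > 1)
      start_polish(starts[[1]]) else starts[[1]]
    out <- .mc_loop(ctx, s0, params, weights,
                    n_steps = params$n_steps, patience = params$patience,
                    start0 = s0, anchor = anchor_pos)
  }
  # final polish of the reported best pose; a clean-slate side-chain
  # repack (template chi, then descent) is tried as well, since squeezed
  # packings can trap an otherwise well-placed pose
  if (params$n_steps > 0) {
  repack <- function(p) {
    tordef <- .default_torsions(list(
      torsion_names = p$torsion_names, torsion_kind = p$torsion_kind,
      torsion_res = p$torsion_res, codes = p$parent_codes))
    chi <- grepl("^chi", p$torsion_kind)
    p$torsions[chi] <- tordef[chi]
    .pose_relax(ctx, rebuild_coords(p), sweeps = 2, bb_lim = 10,
                rigid_lim = 1.2, weights = weights)
  }
  final_set <- function(b) {
    if (use_heavy) list(polish(b), repack(b), polish_zfan(b)) else
      list(polish(b))
  }
  for (it in seq_len(if (use_heavy) 4L else 1L)) {
    improved <- FALSE
    for (fp in final_set(out$best)) {
      fe <- pose_energy(ctx, fp, weights, rebuild = FALSE)
      fobj <- out$track_fn(fp, fe$score)
      if (fobj < out$best_objective - 1e-6) {
        out$best <- fp
        out$best_score <- fe$score
        out$best_objective <- fobj
        fe$breakdown$total <- fe$score
        out$best_breakdown <- fe$breakdown
        out$best_trace <- c(out$best_trace, fobj)
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  }
  out$track_fn <- NULL
  out$seed <- params$seed
  out$params <- params
  class(out) <- "dock_trajectory"
  out
}

# core Metropolis loop (propose -> minimize -> accept), shared by the
# burn-in and main stages
.mc_loop <- function(ctx, start, params, weights, n_steps, patience,
                     start0 = start, anchor = NULL) {
  # stationary part of the restrained objective: poses are ranked by the
  # docking score plus the groove-anchor and starting-conformation
  # restraints, i.e. the objective the restrained search optimizes
  kanc <- params$anchor_k %||% 0
  ktor <- params$restraint_k_torsion %||% 0
  start_bb <- start0$torsions[ctx$bb_idx]
  track <- function(p, score) {
    pen <- 0
    if (!is.null(anchor) && kanc > 0)
      pen <- pen + kanc * sum((colMeans(p$coords) - anchor)^2)
    if (ktor > 0) {
      dv <- .wrap_angle(p$torsions[ctx$bb_idx] - start_bb)
      pen <- pen + ktor * sum(dv^2)
    }
    score + pen
  }
  cur <- rebuild_coords(start)
  pe <- pose_energy(ctx, cur, weights, rebuild = FALSE)
  cur_score <- pe$score
  cur_obj <- track(cur, cur_score)
  best <- cur; best_score <- cur_score; best_obj <- cur_obj
  best_breakdown <- pe$breakdown
  accepted <- list()
  best_trace <- rep(NA_real_, n_steps)
  n_acc <- 0L
  since_best <- 0L
  step <- 0L
  polish_every <- 400L
  repacked <- FALSE
  while (step < n_steps) {
    step <- step + 1L
    if (!repacked && (step == max(1L, n_steps %/% 2L) ||
                        since_best >= patience %/% 2L)) {
      # mid-run rescue: squeezed side-chain packings can trap an almost
      # correctly placed pose against the groove roof or floor. Reset
      # every chi to its template default, scan a fan of vertical
      # offsets, quench each, and adopt the best if it improves; the
      # remaining steps then descend inside the rescued basin.
      repacked <- TRUE
      tordef <- .default_torsions(list(
        torsion_names = cur$torsion_names, torsion_kind = cur$torsion_kind,
        torsion_res = cur$torsion_res, codes = cur$parent_codes))
      chi <- grepl("^chi", cur$torsion_kind)
      for (dz in c(-1, 0, 1, 2, 3)) {
        q <- cur
        q$torsions[chi] <- tordef[chi]
        q$translation[3] <- q$translation[3] + dz
        q <- .pose_relax(ctx, rebuild_coords(q), sweeps = 2, bb_lim = 8,
                         rigid_lim = 1.2, weights = weights)
        qe <- pose_energy(ctx, q, weights, rebuild = FALSE)
        if (track(q, qe$score) < cur_obj) {
          cur <- q
          cur_score <- qe$score
          cur_obj <- track(q, qe$score)
          if (cur_obj < best_obj) {
            best <- cur; best_score <- cur_score; best_obj <- cur_obj
            best_breakdown <- qe$breakdown
            since_best <- 0L
          }
        }
      }
    }
    if (step %% polish_every == 0L) {
      # periodic deterministic quench pulls the walk to its basin floor
      q <- .pose_relax(ctx, cur, sweeps = 1, bb_lim = 8, rigid_lim = 0.6,
                       weights = weights)
      qe <- pose_energy(ctx, q, weights, rebuild = FALSE)
      if (track(q, qe$score) < cur_obj) {
        cur <- q
        cur_score <- qe$score
        cur_obj <- track(q, qe$score)
        if (cur_obj < best_obj) {
          best <- cur; best_score <- cur_score; best_obj <- cur_obj
          best_breakdown <- qe$breakdown
          since_best <- 0L
        }
      }
    }
    prop <- propose_move(cur, params, ctx = ctx, reference = cur,
                         start = start0, anchor = anchor)
    if (!is.finite(prop$dG)) { since_best <- since_best + 1L; next }
    if (metropolis_accept(prop$dG, params)) {
      cur <- prop$conf
      pe <- pose_energy(ctx, cur, weights, rebuild = FALSE)
      cur_score <- pe$score
      n_acc <- n_acc + 1L
      accepted[[length(accepted) + 1]] <- c(step = step, score = cur_score)
      cur_obj <- track(cur, cur_score)
      if (cur_obj < best_obj) {
        best <- cur; best_score <- cur_score; best_obj <- cur_obj
        best_breakdown <- pe$breakdown
        since_best <- 0L
      } else since_best <- since_best + 1L
    } else since_best <- since_best + 1L
    best_trace[step] <- best_obj
    if (since_best >= patience) break
  }
  acc_df <- if (length(accepted)) {
    as.data.frame(do.call(rbind, accepted))
  } else data.frame(step = integer(0), score = numeric(0))
  bt <- best_trace[seq_len(step)]
  list(best = best, best_score = best_score, best_objective = best_obj,
       track_fn = track, start_pose = rebuild_coords(start),
       best_breakdown = best_breakdown, final = cur, accepted = acc_df,
       best_trace = bt[!is.na(bt)], acceptance_count = n_acc,
       steps_run = step)
}

#' @export
print.dock_trajectory <- function(x, ...) {
  cat(sprintf(
    "dock_trajectory: %d steps, %d accepted, best score %.3f kcal/mol\n",
    x$steps_run, x$acceptance_count, x$best_score))
  invisible(x)
}
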