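# Synthetic mini-groove generator: a small, chemically plausible peptide
# binding groove (two antiparallel helical walls over a strand floor with
# pocket cavities) plus a native peptide pose with known ground truth, so
# the whole docking stack is testable without downloading structures.

#' Specification of a synthetic mini-groove fixture
#'
#' @param seed Integer seed; the generator is fully deterministic per
#'   spec.
#' @param peptide_length Peptide length (8--15 at desk scale; lengths
#'   above 9 get flanking residues outside the groove walls).
#' @param register Requested 1-based core start for peptides longer than
#'   9 (default: drawn from the seeded RNG).
#' @param pocket_count Number of floor pocket cavities (2 or 3).
#' @param groove_half_width Distance from the groove axis to each helix
#'   wall axis (Angstrom).
#' @param noise_sd Gaussian jitter applied to receptor coordinates
#'   (Angstrom).
#' @param mhc_class "I" or "II" (sets the docking-box defaults used
#'   downstream).
#' @param core_sequence Nonameric core sequence placed in the groove.
#'   Position 1 carries a charged anchor paired with an end-pocket
#'   glutamate, the pocket anchors sit at core positions 2 and 4 (make 4
#'   bulky), and positions 3, 5 and 7 should be small so they fit under
#'   the groove roof.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 42, peptide_length = 9, register = NULL,
                         pocket_count = 2, groove_half_width = 7.0,
                         noise_sd = 0.05, mhc_class = "I",
                         core_sequence = "KLAWAVSTL") {
  stopifnot(peptide_length >= 8, peptide_length <= 15,
            nchar(core_sequence) == 9, noise_sd >= 0,
            mhc_class %in% c("I", "II"))
  if (!is.null(register)) {
    stopifnot(register >= 1,
              register <= max(1, peptide_length - 8))
  }
  structure(list(seed = seed, peptide_length = peptide_length,
                 register = register, pocket_count = pocket_count,
                 groove_half_width = groove_half_width,
                 noise_sd = noise_sd, mhc_class = mhc_class,
                 core_sequence = core_sequence), class = "fixture_spec")
}

# build a chain, align its CA principal axis to +x (N->C pointing +x)
# and center the CA centroid at the origin
.aligned_chain <- function(codes, phi, psi, center_idx = NULL) {
  tor <- NULL
  p <- peptide_conformation(codes)
  t <- p$torsions
  t[p$torsion_kind == "phi"] <- phi
  t[p$torsion_kind == "psi"] <- psi
  t[p$torsion_kind == "omega"] <- 180
  p$torsions <- t
  p <- rebuild_coords(p)
  ca <- p$coords[p$ca_idx, , drop = FALSE]
  use <- if (is.null(center_idx)) seq_len(nrow(ca)) else center_idx
  v <- stats::prcomp(ca)$rotation[, 1]
  if (sum(v * (ca[nrow(ca), ] - ca[1, ])) < 0) v <- -v
  R <- .rotation_between(v, c(1, 0, 0))
  p$rotation <- R %*% p$rotation
  p$translation <- as.numeric(R %*% p$translation)
  p <- rebuild_coords(p)
  cen <- colMeans(p$coords[p$ca_idx, , drop = FALSE][use, , drop = FALSE])
  p$translation <- p$translation - cen
  rebuild_coords(p)
}

.rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  ax <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(ax^2)); c0 <- sum(a * b)
  if (s < 1e-9) {
    if (c0 > 0) return(diag(3))
    perp <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- perp - sum(perp * a) * a
    return(.rot_axis(ax, 180))
  }
  .rot_axis(ax, atan2(s, c0) * 180 / pi)
}

.shift <- function(p, d) {
  p$translation <- p$translation + d
  rebuild_coords(p)
}

.conf_to_atoms <- function(p, chain, resno0 = 0L) {
  data.frame(elety = p$atoms$name, resid = p$codes[p$atoms$residue_index],
             chain = chain, resno = p$atoms$residue_index + resno0,
             x = p$coords[, 1], y = p$coords[, 2], z = p$coords[, 3],
             o = 1, is_hetero = FALSE, stringsAsFactors = FALSE)
}


# Mutate selected wall residues and aim their functional tips at target
# atoms by a deterministic discrete chi scan; clamps that cannot avoid
# clashes revert to alanine.
.aim_residues <- function(wall, picks, code, tip_names, target_xyz,
                          pep, other) {
  if (!length(picks)) return(wall)
  codes <- wall$parent_codes
  codes[picks] <- code
  new_wall <- peptide_conformation(codes, rotation = wall$rotation,
                                   translation = wall$translation)
  shared <- intersect(names(wall$torsions), names(new_wall$torsions))
  new_wall$torsions[shared] <- wall$torsions[shared]
  new_wall <- rebuild_coords(new_wall)
  other <- as.matrix(other)
  nchi <- sum(grepl("^chi", new_wall$torsion_kind) &
                new_wall$torsion_res == picks[1])
  revert <- integer(0)
  for (r in picks) {
    tn <- paste0("chi", seq_len(nchi), "_", r)
    tn <- tn[tn %in% names(new_wall$torsions)]
    side_idx <- which(new_wall$atoms$residue_index == r &
                        !(new_wall$atoms$name %in% c("N", "CA", "C", "O",
                                                     "CB")))
    self_idx <- which(abs(new_wall$atoms$residue_index - r) >= 2L)
    grid <- list(seq(-150, 180, by = 30), seq(-150, 180, by = 30),
                 c(-90, 0, 90, 180), c(-90, 0, 90, 180))[seq_along(tn)]
    combos <- do.call(expand.grid, grid)
    best <- NULL; best_s <- Inf
    for (ci in seq_len(nrow(combos))) {
      new_wall$torsions[tn] <- as.numeric(combos[ci, ])
      new_wall <- rebuild_coords(new_wall)
      sxyz <- new_wall$coords[side_idx, , drop = FALSE]
      tips <- sxyz[new_wall$atoms$name[side_idx] %in% tip_names, ,
                   drop = FALSE]
      dtip <- apply(tips, 1, function(p)
        min(sqrt(colSums((t(target_xyz) - p)^2))))
      dpep <- min(apply(sxyz, 1, function(p)
        min(sqrt(colSums((t(pep$coords) - p)^2)))))
      doth <- min(apply(sxyz, 1, function(p)
        min(sqrt(colSums((t(other) - p)^2)))))
      dself <- min(apply(sxyz, 1, function(p)
        min(sqrt(colSums((t(new_wall$coords[self_idx, , drop = FALSE]) -
                            p)^2)))))
      sc <- sum(abs(dtip - 2.9)) + 100 * (dpep < 3.0) +
        100 * (doth < 2.9) + 100 * (dself < 2.9)
      if (sc < best_s) { best_s <- sc; best <- as.numeric(combos[ci, ]) }
    }
    if (best_s >= 100) {
      revert <- c(revert, r)
    } else {
      new_wall$torsions[tn] <- best
      new_wall <- rebuild_coords(new_wall)
    }
  }
  if (length(revert)) {
    codes[revert] <- "ALA"
    final <- peptide_conformation(codes, rotation = wall$rotation,
                                  translation = wall$translation)
    shared <- intersect(names(new_wall$torsions), names(final$torsions))
    final$torsions[shared] <- new_wall$torsions[shared]
    return(rebuild_coords(final))
  }
  new_wall
}

# Backbone clamps: inward-facing alanines become glutamines aimed at the
# native peptide backbone (the analogue of the conserved polar residues
# lining real MHC grooves).
.add_backbone_clamps <- function(wall, pep, inward, other, n_clamps = 3) {
  geo <- .wall_geometry(wall, pep, inward)
  if (!length(geo$cand)) return(wall)
  ca <- geo$ca
  targets <- stats::quantile(range(ca[, 1]), c(0.25, 0.5, 0.75))
  picks <- integer(0)
  for (t in targets[seq_len(min(n_clamps, length(targets)))]) {
    left <- setdiff(geo$cand, picks)
    if (!length(left)) break
    picks <- c(picks, left[which.min(abs(ca[left, 1] - t))])
  }
  pep_no <- pep$coords[pep$atoms$name %in% c("N", "O"), , drop = FALSE]
  .aim_residues(wall, picks, "GLN", c("OE1", "NE2"), pep_no, pep, other)
}

# Terminal locks: a glutamate aimed at the ammonium N-terminus and an
# arginine aimed at the carboxylate C-terminus (end-pocket analogues).
.add_terminal_lock <- function(wall, pep, inward, other, terminus) {
  geo <- .wall_geometry(wall, pep, inward, min_inward = 0.2,
                        reach_min = 3.5, reach_max = 11)
  if (!length(geo$cand)) return(wall)
  if (terminus == "N") {
    target <- pep$coords[which(pep$atoms$residue_index == 1L &
                                 pep$atoms$name == "N"), , drop = FALSE]
    code <- "GLU"; tips <- c("OE1", "OE2")
  } else {
    target <- pep$coords[which(pep$atoms$residue_index == pep$nres &
                                 pep$atoms$name == "O"), , drop = FALSE]
    code <- "ARG"; tips <- c("NH1", "NH2")
  }
  d <- sqrt(colSums((t(geo$ca[geo$cand, , drop = FALSE]) -
                       as.numeric(target))^2))
  pick <- geo$cand[which.min(d)]
  if (min(d) > 11) return(wall)
  .aim_residues(wall, pick, code, tips, target, pep, other)
}

.wall_geometry <- function(wall, pep, inward, min_inward = 0.55,
                           reach_min = 4.0, reach_max = 8.5) {
  ca <- wall$coords[wall$ca_idx, , drop = FALSE]
  cb <- matrix(NA_real_, wall$nres, 3)
  for (r in seq_len(wall$nres)) {
    w <- which(wall$atoms$residue_index == r & wall$atoms$name == "CB")
    if (length(w)) cb[r, ] <- wall$coords[w[1], ]
  }
  dirs <- cb - ca
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pep_bb <- pep$coords[pep$atoms$name %in% c("N", "CA", "C", "O"), ,
                       drop = FALSE]
  reach <- rep(NA_real_, wall$nres)
  for (r in seq_len(wall$nres)) {
    if (is.na(cb[r, 1])) next
    reach[r] <- min(sqrt(colSums((t(pep_bb) - cb[r, ])^2)))
  }
  cand <- which(!is.na(dirs[, 2]) & inward * dirs[, 2] > min_inward &
                  wall$parent_codes == "ALA" & reach > reach_min &
                  reach < reach_max)
  list(ca = ca, cb = cb, dirs = dirs, cand = cand, reach = reach)
}


# Local coordinate-descent relaxation of the native pose in the docking
# energy model: rigid-body placement (small windows) and side-chain chi
# angles only; the extended backbone of the construction is preserved.
.settle_native <- function(maps, pep, sweeps = 3) {
  ctx <- dock_context(maps, pep)
  # restrained to the constructed pose: settling polishes, it must not
  # migrate
  .pose_relax(ctx, pep, sweeps = sweeps, bb_lim = 12,
              ref_ca = pep$coords[pep$ca_idx, , drop = FALSE],
              ref_k = 0.5)
}


# drop whole residues of `new_atoms` that collide with already-placed
# receptor atoms
.prune_overlaps <- function(new_atoms, existing_xyz, cut = 2.2) {
  if (is.null(new_atoms) || !nrow(new_atoms)) return(new_atoms)
  d <- .min_cross_dist(as.matrix(new_atoms[, c("x", "y", "z")]),
                       as.matrix(existing_xyz))
  key <- paste(new_atoms$chain, new_atoms$resno)
  bad <- unique(key[d < cut])
  new_atoms[!(key %in% bad), , drop = FALSE]
}

aa_bulky_codes <- function(codes) {
  codes %in% c("PHE", "TYR", "TRP", "ARG", "LYS", "MET", "LEU", "ILE",
               "GLN", "GLU")
}

#' Generate a synthetic mini-groove complex with ground truth
#'
#' Builds a receptor of two antiparallel poly-alanine helices (leucine
#' lining, one glutamate facing the charged peptide anchor) flanking a
#' four-strand floor with glycine pocket cavities, and places a native
#' peptide pose in the groove: extended backbone along the groove axis,
#' pocket-anchor side chains pointing into the floor cavities. For
#' peptides longer than 9 residues the walls cover only the nonameric
#' core, and the true register is recorded. The output is byte-identical
#' for identical specs.
#'
#' @param spec A `fixture_spec`.
#' @param dir Optional directory; when given, writes `mini_groove.pdb`
#'   and `mini_groove_truth.json` there.
#' @return list with `complex` (a `pmhc`), `truth` (seed, sequence,
#'   register, anchors, native torsions and native C-alpha coordinates)
#'   and `native` (the native `peptide_conformation`).
#' @export
generate_mini_groove <- function(spec = fixture_spec(), dir = NULL) {
  set.seed(spec$seed)
  L <- spec$peptide_length
  core <- strsplit(spec$core_sequence, "")[[1]]
  reg <- if (L <= 9) 1L else
    if (!is.null(spec$register)) as.integer(spec$register) else
      sample(seq_len(L - 8L), 1)
  flank_pool <- c("A", "S", "G", "T", "N")
  left <- if (reg > 1) sample(flank_pool, reg - 1, replace = TRUE) else
    character(0)
  nright <- L - 9L - (reg - 1L)
  right <- if (nright > 0) sample(flank_pool, nright, replace = TRUE) else
    character(0)
  seq1 <- c(left, if (L >= 9) core else core[seq_len(L)], right)
  if (L < 9) reg <- 1L
  pep_seq <- paste(seq1, collapse = "")
  core_pos <- if (L <= 9) seq_len(L) else reg:(reg + 8L)
  # pocket anchors: even core positions for 9-mers; odd positions for
  # longer peptides so that both core ends point into the floor and the
  # flanking residues adjacent to the core point away from it -- this
  # makes the bound register unambiguous for contact counting
  anchor_pos <- if (L <= 9) c(2, 4, if (spec$pocket_count >= 3) 6) else
    c(3, 5, if (spec$pocket_count >= 3) 7)
  anchors <- core_pos[anchor_pos]
  anchors <- anchors[!is.na(anchors)]

  # native peptide: extended backbone, near-staggered side chains
  pep <- peptide_conformation(bio3d::aa123(seq1))
  tor <- pep$torsions
  tor[pep$torsion_kind == "phi"] <- -139
  tor[pep$torsion_kind == "psi"] <- 135
  tor[pep$torsion_kind == "omega"] <- 180
  chi <- grepl("^chi", pep$torsion_kind) &
    pep$parent_codes[pep$torsion_res] != "PRO"
  tor[chi] <- .wrap_angle(tor[chi] + stats::runif(sum(chi), -8, 8))
  pep$torsions <- tor
  pep <- rebuild_coords(pep)
  # align core CA axis to +x, core centroid at origin
  ca <- pep$coords[pep$ca_idx, , drop = FALSE]
  v <- stats::prcomp(ca[core_pos, , drop = FALSE])$rotation[, 1]
  if (sum(v * (ca[max(core_pos), ] - ca[min(core_pos), ])) < 0) v <- -v
  R <- .rotation_between(v, c(1, 0, 0))
  pep$rotation <- R %*% pep$rotation
  pep$translation <- as.numeric(R %*% pep$translation)
  pep <- rebuild_coords(pep)
  cen <- colMeans(pep$coords[pep$ca_idx, , drop = FALSE][core_pos, ,
                                                         drop = FALSE])
  pep$translation <- pep$translation - cen
  pep <- rebuild_coords(pep)
  # roll about x so the anchor side chains point down (-z)
  tip <- which(pep$atoms$residue_index %in% anchors &
                 !(pep$atoms$name %in% c("N", "CA", "C", "O")))
  best_ang <- 0; best_z <- Inf
  for (ang in seq(0, 358, by = 2)) {
    Rx <- .rot_axis(c(1, 0, 0), ang)
    z <- mean((pep$coords[tip, , drop = FALSE] %*% t(Rx))[, 3])
    if (z < best_z) { best_z <- z; best_ang <- ang }
  }
  Rx <- .rot_axis(c(1, 0, 0), best_ang)
  pep$rotation <- Rx %*% pep$rotation
  pep$translation <- as.numeric(Rx %*% pep$translation)
  pep <- rebuild_coords(pep)

  anchor_x <- pep$coords[pep$ca_idx, 1][anchors]
  # floor cavities: under the anchors for 9-mers; for longer peptides
  # under every down-facing residue (odd core positions plus same-parity
  # flanking residues), so that flanks never jam against the floor
  down_pos <- if (L <= 9) anchors else
    which((seq_len(L) - reg) %% 2 == 0)
  cavity_x <- pep$coords[pep$ca_idx, 1][down_pos]
  cavity_wide <- aa_bulky_codes(pep$parent_codes[down_pos])
  k1_x <- pep$coords[pep$ca_idx, 1][core_pos[1]]

  # helical walls (19 residues ~ the core span), leucine-lined
  wall_seq <- rep("ALA", 19)
  wall_seq[c(4, 8, 12, 16)] <- "LEU"
  w <- spec$groove_half_width
  wallA <- .aligned_chain(wall_seq, -57, -47)
  wallA <- .shift(wallA, c(0, w, -1))
  wallB <- .aligned_chain(wall_seq, -57, -47)
  wallB$rotation <- .rot_axis(c(0, 0, 1), 180) %*% wallB$rotation
  wallB$translation <- as.numeric(.rot_axis(c(0, 0, 1), 180) %*%
                                    wallB$translation)
  wallB <- rebuild_coords(wallB)
  wallB <- .shift(wallB, c(0, -w, -1))

  # floor: three extended strands at sheet-like spacing; glycine
  # cavities under the anchors on the central strand, leucine lining on
  # the outer strands
  strand_y <- c(-4.9, 0, 4.9)
  resno0 <- 0L
  floor_atoms <- NULL
  for (si in seq_along(strand_y)) {
    codes <- rep("ALA", 9)
    strand_x <- (seq_len(9) - 5) * 3.45
    # antiparallel strands are mirrored in x by the flip below
    eff_x <- if (si %% 2 == 0) -strand_x else strand_x
    central <- si == 2
    # cavity width follows side-chain bulk: bulky residues need a wide
    # cavity, small ones a narrow one -- this shape asymmetry (plus the
    # terminal charges) fixes the binding direction
    for (j in seq_len(9)) {
      dx <- abs(eff_x[j] - cavity_x)
      if (central && any(dx < ifelse(cavity_wide, 3.6, 2.4)))
        codes[j] <- "GLY"
      if (!central && min(abs(eff_x[j] - anchor_x)) < 2.6)
        codes[j] <- "LEU"
    }
    st <- .aligned_chain(codes, -139, 135)
    # roll the strand so carbonyls lie in the sheet plane (as in a real
    # beta sheet), leaving the pleated CBs to face up/down
    co <- which(st$atoms$name == "O")
    cc <- which(st$atoms$name == "C")
    best_a <- 0; best_v <- Inf
    for (ang in seq(0, 178, by = 2)) {
      Rx <- .rot_axis(c(1, 0, 0), ang)
      dz <- (st$coords[co, , drop = FALSE] %*% t(Rx))[, 3] -
        (st$coords[cc, , drop = FALSE] %*% t(Rx))[, 3]
      v <- sum(dz^2)
      if (v < best_v) { best_v <- v; best_a <- ang }
    }
    Rx <- .rot_axis(c(1, 0, 0), best_a)
    st$rotation <- Rx %*% st$rotation
    st$translation <- as.numeric(Rx %*% st$translation)
    st <- rebuild_coords(st)
    if (si %% 2 == 0) {  # antiparallel sheet
      st$rotation <- .rot_axis(c(0, 0, 1), 180) %*% st$rotation
      st$translation <- as.numeric(.rot_axis(c(0, 0, 1), 180) %*%
                                     st$translation)
      st <- rebuild_coords(st)
    }
    st <- .shift(st, c(0, strand_y[si], spec$floor_z %||% -7.5))
    floor_atoms <- rbind(floor_atoms, .conf_to_atoms(st, "C", resno0))
    resno0 <- resno0 + 9L
  }

  # floor residues that collide with the walls are pruned
  wall_xyz <- rbind(
    data.frame(x = wallA$coords[, 1], y = wallA$coords[, 2],
               z = wallA$coords[, 3]),
    data.frame(x = wallB$coords[, 1], y = wallB$coords[, 2],
               z = wallB$coords[, 3]))
  floor_atoms <- .prune_overlaps(floor_atoms, wall_xyz)

  # polar clamps: inward-facing wall positions become glutamines whose
  # amide groups hydrogen-bond the native peptide backbone -- the fixture
  # analogue of the conserved polar residues lining real MHC grooves.
  # They pin the bound peptide height and register.
  ctxB <- rbind(.conf_to_atoms(wallB, "B"), floor_atoms)
  wallA <- .add_backbone_clamps(wallA, pep, inward = -1,
                                other = ctxB[, c("x", "y", "z")])
  wallA <- .add_terminal_lock(wallA, pep, inward = -1,
                              other = ctxB[, c("x", "y", "z")],
                              terminus = "N")
  ctxA <- rbind(.conf_to_atoms(wallA, "A"), floor_atoms)
  wallB <- .add_backbone_clamps(wallB, pep, inward = +1,
                                other = ctxA[, c("x", "y", "z")])
  wallB <- .add_terminal_lock(wallB, pep, inward = +1,
                              other = ctxA[, c("x", "y", "z")],
                              terminus = "C")

  rec_atoms <- rbind(.conf_to_atoms(wallA, "A"),
                     .conf_to_atoms(wallB, "B"), floor_atoms)

  # closed groove ends for class-I-like fixtures: stacked helical plugs
  # block the groove beyond the peptide termini (the analogue of the
  # closed A/F ends of a class I cleft), so bound 9-mers cannot slide
  # along the groove axis or pitch over the ends. The N-terminal end
  # pocket carries a glutamate coordinating the ammonium terminus, the
  # C-terminal end an arginine that salt-bridges the carboxylate,
  # locking the binding direction. Longer peptides keep an open groove
  # so their flanking residues can protrude.
  if (L <= 9) {
    xmax <- max(abs(pep$coords[, 1]))
    # every plug gets its own short chain so peptide auto-detection can
    # never mistake a plug for the bound peptide
    cap_chain <- list(c("D", "E", "G"), c("H", "I", "J"))
    nterm_xyz <- pep$coords[which(pep$atoms$residue_index == 1L &
                                    pep$atoms$name == "N"), , drop = FALSE]
    cterm_xyz <- pep$coords[which(pep$atoms$residue_index == pep$nres &
                                    pep$atoms$name == "O"), , drop = FALSE]
    for (si in 1:2) {
      sgn <- c(-1, 1)[si]
      nterm_side <- sgn * mean(pep$coords[pep$atoms$residue_index == 1L,
                                          1]) < 0
      cap_z <- spec$cap_z %||% c(-4.5, -0.5, 2.0)
      for (k in seq_along(cap_z)) {
        zc <- cap_z[k]
        cap <- .aligned_chain(rep("ALA", 5), -57, -47)
        Rz <- .rot_axis(c(0, 0, 1), 90)
        cap$rotation <- Rz %*% cap$rotation
        cap$translation <- as.numeric(Rz %*% cap$translation)
        cap <- rebuild_coords(cap)
        cx0 <- xmax + 1.5
        repeat {
          trial <- .shift(cap, c(sgn * cx0, 0, zc))
          if (min(.min_cross_dist(trial$coords, pep$coords)) >= 2.8) {
            cap <- trial
            break
          }
          cx0 <- cx0 + 0.25
        }
        plug <- .prune_overlaps(.conf_to_atoms(cap, cap_chain[[si]][k]),
                                rec_atoms[, c("x", "y", "z")])
        if (k == 2L && any(plug$resno == 3L)) {
          # middle plug sits at the terminus level; aim its center
          cap <- if (nterm_side) {
            .aim_residues(cap, 3L, "GLU", c("OE1", "OE2"), nterm_xyz,
                          pep, rec_atoms[, c("x", "y", "z")])
          } else {
            .aim_residues(cap, 3L, "ARG", c("NH1", "NH2"), cterm_xyz,
                          pep, rec_atoms[, c("x", "y", "z")])
          }
          plug <- .prune_overlaps(.conf_to_atoms(cap, cap_chain[[si]][k]),
                                  rec_atoms[, c("x", "y", "z")])
        }
        rec_atoms <- rbind(rec_atoms, plug)
      }
    }
  }

  # roof plugs over the groove: short helical bridges above the small
  # up-facing core positions, like the inter-pocket ridges of a real
  # groove roof. The native small side chains clear them; reversed or
  # rolled peptides must put bulky side chains there and cannot
  if (L <= 9) {
    x3 <- pep$coords[pep$ca_idx[core_pos[3]], 1]
    x5 <- pep$coords[pep$ca_idx[core_pos[5]], 1]
    x7 <- pep$coords[pep$ca_idx[core_pos[7]], 1]
    roof_x <- c(x3 - 3.5, x3, (x3 + x5) / 2, x5, (x5 + x7) / 2, x7)
    for (ri in seq_along(roof_x)) {
      ridge <- .aligned_chain(rep("ALA", 4), -57, -47)
      Rz <- .rot_axis(c(0, 0, 1), 90)
      ridge$rotation <- Rz %*% ridge$rotation
      ridge$translation <- as.numeric(Rz %*% ridge$translation)
      ridge <- rebuild_coords(ridge)
      z0 <- 2.8
      repeat {
        trial <- .shift(ridge, c(roof_x[ri], 0, z0))
        if (min(.min_cross_dist(trial$coords, pep$coords)) >= 2.9) {
          ridge <- trial
          break
        }
        z0 <- z0 + 0.25
      }
      plug <- .prune_overlaps(
        .conf_to_atoms(ridge, c("K", "M", "Q", "T", "U", "V")[ri]),
        rec_atoms[, c("x", "y", "z")])
      rec_atoms <- rbind(rec_atoms, plug)
    }
  }
  if (spec$noise_sd > 0) {
    jit <- matrix(stats::rnorm(3 * nrow(rec_atoms), 0, spec$noise_sd),
                  ncol = 3)
    rec_atoms$x <- rec_atoms$x + jit[, 1]
    rec_atoms$y <- rec_atoms$y + jit[, 2]
    rec_atoms$z <- rec_atoms$z + jit[, 3]
  }
  # accommodate the bound peptide: the rare receptor side chain that the
  # construction leaves overlapping the native peptide is pruned to
  # glycine
  side_rows <- !(rec_atoms$elety %in% c("N", "CA", "C", "O"))
  dmin <- .min_cross_dist(as.matrix(rec_atoms[, c("x", "y", "z")]),
                          pep$coords)
  key <- paste(rec_atoms$chain, rec_atoms$resno)
  bad <- unique(key[side_rows & dmin < 2.7])
  if (length(bad)) {
    rec_atoms$resid[key %in% bad] <- "GLY"
    rec_atoms <- rec_atoms[!(side_rows & key %in% bad), , drop = FALSE]
  }

  # settle the native pose: a small deterministic relaxation of the
  # rigid-body placement and side-chain chi angles inside the assembled
  # groove, so the recorded ground truth is mechanically stable in the
  # docking energy model (the role a crystal pose plays for a physical
  # force field)
  rec_atoms$groove <- TRUE
  box <- make_docking_box(rec_atoms, spec$mhc_class)
  site <- select_binding_site(rec_atoms, box)
  maps <- build_grid_maps(rec_atoms, site, box)
  pep <- .settle_native(maps, pep)
  rec_atoms$groove <- NULL

  # settling can bring previously clear receptor side chains into
  # contact; prune those too
  side_rows <- !(rec_atoms$elety %in% c("N", "CA", "C", "O"))
  dmin <- .min_cross_dist(as.matrix(rec_atoms[, c("x", "y", "z")]),
                          pep$coords)
  key <- paste(rec_atoms$chain, rec_atoms$resno)
  bad <- unique(key[side_rows & dmin < 2.7])
  if (length(bad)) {
    rec_atoms$resid[key %in% bad] <- "GLY"
    rec_atoms <- rec_atoms[!(side_rows & key %in% bad), , drop = FALSE]
  }

  pep_atoms <- .conf_to_atoms(pep, "P")
  # construction sanity: the native peptide must sit clash-free
  mind <- .min_cross_dist(as.matrix(rec_atoms[, c("x", "y", "z")]),
                          pep$coords)
  if (min(mind) < (spec$min_clearance %||% 2.30))
    stop("infeasible fixture geometry: groove too narrow for the peptide ",
         sprintf("(min receptor-peptide distance %.2f A)", min(mind)))
  atoms <- rbind(rec_atoms, pep_atoms)
  atoms$x <- round(atoms$x, 3); atoms$y <- round(atoms$y, 3)
  atoms$z <- round(atoms$z, 3)
  cx <- as_pmhc(atoms, peptide_chain = "P", mhc_class = spec$mhc_class,
                allele = "synthetic-groove")
  truth <- list(seed = spec$seed, sequence = pep_seq, register = reg,
                anchors = anchors,
                native_torsions = pep$torsions,
                native_ca = pep$coords[pep$ca_idx, , drop = FALSE],
                core_positions = core_pos,
                spec = unclass(spec))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_pdb_file(cx, file.path(dir, "mini_groove.pdb"))
    jsonlite::write_json(
      truth, file.path(dir, "mini_groove_truth.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(complex = cx, truth = truth, native = pep)
}
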