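# Docking box, binding-site selection and grid potential maps.

#' Standardized docking-box dimensions
#'
#' Class defaults derived from surveys of crystallographic pMHC grooves:
#' 35.36 x 35.52 x 35.79 A for MHC class I and 58.32 x 56.36 x 48.87 A
#' for class II.
#'
#' @param mhc_class "I" or "II".
#' @return Numeric length-3 (length, breadth, height) in Angstrom.
#' @export
class_box_dims <- function(mhc_class) {
  switch(mhc_class,
         "I" = c(35.36, 35.52, 35.79),
         "II" = c(58.32, 56.36, 48.87),
         stop("unknown MHC class '", mhc_class,
              "'; supply override_dims explicitly"))
}

#' Define the docking box over the binding groove
#'
#' Centers the box at the centroid of the groove-domain C-alpha atoms and
#' applies the standardized class dimensions (or an override). If any
#' groove atom falls outside, the box is expanded to enclose it (with a
#' warning).
#'
#' @param receptor Receptor atom data.frame (with a logical `groove`
#'   column) or a `pmhc` complex.
#' @param mhc_class "I" or "II" (taken from the complex when omitted).
#' @param override_dims Optional explicit (length, breadth, height).
#' @param center Optional explicit center (overrides the groove centroid).
#' @return list of class `docking_box`: `center`, `dims`, `mhc_class`.
#' @export
make_docking_box <- function(receptor, mhc_class = NULL,
                             override_dims = NULL, center = NULL) {
  if (inherits(receptor, "pmhc")) {
    if (is.null(mhc_class)) mhc_class <- receptor$mhc_class
    atoms <- receptor$atoms[receptor$receptor_idx, , drop = FALSE]
    atoms$groove <- receptor$groove[receptor$receptor_idx]
    receptor <- atoms
  }
  if (is.null(receptor$groove)) receptor$groove <- TRUE
  dims <- if (!is.null(override_dims)) as.numeric(override_dims) else
    class_box_dims(mhc_class)
  gca <- receptor[receptor$groove & receptor$elety == "CA", , drop = FALSE]
  if (!nrow(gca)) gca <- receptor[receptor$elety == "CA", , drop = FALSE]
  if (is.null(center)) center <- colMeans(as.matrix(gca[, c("x", "y", "z")]))
  gxyz <- as.matrix(receptor[receptor$groove, c("x", "y", "z")])
  need <- 2 * apply(abs(sweep(gxyz, 2, center)), 2, max)
  if (any(need > dims)) {
    warning("docking box expanded to enclose all binding-site atoms")
    dims <- pmax(dims, need + 0.5)
  }
  structure(list(center = as.numeric(center), dims = dims,
                 mhc_class = mhc_class), class = "docking_box")
}

#' Select binding-site atoms with groove spheres
#'
#' Lays sphere centers along the first principal axis of the groove
#' C-alpha cloud (five centers spanning the central 60% of the box length
#' by default) and selects every receptor atom lying in or on a sphere of
#' the given radius.
#'
#' @param receptor Receptor atom data.frame (optionally with `groove`).
#' @param box A `docking_box`.
#' @param radius Sphere radius in Angstrom (default 5.00).
#' @param n_centers Number of sphere centers.
#' @return list of class `binding_site`: `atom_idx` (rows of `receptor`),
#'   `centers`, `radius` and a coordinate snapshot `coords` of the
#'   selected atoms.
#' @export
select_binding_site <- function(receptor, box, radius = 5.00,
                                n_centers = 5) {
  if (is.null(receptor$groove)) receptor$groove <- TRUE
  rxyz <- as.matrix(receptor[, c("x", "y", "z")])
  gca <- receptor$groove & receptor$elety == "CA"
  axis_src <- rxyz[if (any(gca)) gca else receptor$elety == "CA", ,
                   drop = FALSE]
  ax <- if (nrow(axis_src) > 2) stats::prcomp(axis_src)$rotation[, 1] else
    c(1, 0, 0)
  span <- 0.6 * box$dims[1]
  offs <- seq(-span / 2, span / 2, length.out = n_centers)
  centers <- t(vapply(offs, function(s) box$center + s * ax, numeric(3)))
  mind <- rep(Inf, nrow(rxyz))
  for (i in seq_len(nrow(centers))) {
    d <- sqrt(colSums((t(rxyz) - centers[i, ])^2))
    mind <- pmin(mind, d)
  }
  idx <- which(mind <= radius + 1e-9)  # "in and on" the spheres
  if (!length(idx)) warning("binding-site selection is empty")
  structure(list(atom_idx = idx, centers = centers, radius = radius,
                 coords = rxyz[idx, , drop = FALSE],
                 resno = receptor$resno[idx], chain = receptor$chain[idx]),
            class = "binding_site")
}

#' Precompute receptor grid potential maps
#'
#' Evaluates the receptor interaction field on a regular grid (1.00 A
#' spacing by default) over the docking box, one 3-D array per channel:
#' split attractive/repulsive van der Waals (the steep wall is smoothly
#' capped so it interpolates stably), electrostatic potential (per unit
#' probe charge, epsilon = 4r), hydrogen-bond donor and acceptor wells,
#' the hydrophobic contact field, and a burial count used by the fast
#' solvation/entropy estimates. The field includes binding-site atoms
#' plus all receptor atoms within 8 A of the box.
#'
#' @param receptor Receptor atom data.frame.
#' @param site A `binding_site`.
#' @param box A `docking_box`.
#' @param ff Force field.
#' @param spacing Grid spacing in Angstrom.
#' @return list of class `grid_maps`: `origin`, `spacing`, `npts` (nodes
#'   per axis), `channels` (named list of 3-D arrays), `box`, and the
#'   receptor subset used.
#' @export
build_grid_maps <- function(receptor, site, box, ff = default_forcefield(),
                            spacing = 1.00) {
  if (!length(site$atom_idx)) stop("binding site is empty")
  npts <- floor(box$dims / spacing) + 1L
  origin <- box$center - (npts - 1L) * spacing / 2
  lo <- origin - 8; hi <- origin + (npts - 1L) * spacing + 8
  rxyz <- as.matrix(receptor[, c("x", "y", "z")])
  near_box <- rxyz[, 1] >= lo[1] & rxyz[, 1] <= hi[1] &
    rxyz[, 2] >= lo[2] & rxyz[, 2] <= hi[2] &
    rxyz[, 3] >= lo[3] & rxyz[, 3] <= hi[3]
  sel <- sort(union(site$atom_idx, which(near_box)))
  sub <- receptor[sel, , drop = FALSE]
  rset <- .atoms_df_to_set(sub, ff)
  # expand.grid varies x fastest, matching the array linear index order
  nodes <- as.matrix(expand.grid(
    x = origin[1] + spacing * (seq_len(npts[1]) - 1L),
    y = origin[2] + spacing * (seq_len(npts[2]) - 1L),
    z = origin[3] + spacing * (seq_len(npts[3]) - 1L)))
  fld <- receptor_field_cpp(nodes, rset$xyz, rset$cls, rset$charge,
                            as.integer(rset$donor), as.integer(rset$donp),
                            as.integer(rset$acceptor),
                            as.integer(rset$apolar), .ff_cpp(ff))
  ch_names <- c("vdw_attractive", "vdw_repulsive", "electrostatic",
                "hbond_donor", "hbond_acceptor", "hydrophobic", "burial")
  channels <- lapply(seq_along(ch_names), function(c)
    array(fld[, c], dim = npts))
  names(channels) <- ch_names
  axis <- site$centers[nrow(site$centers), ] - site$centers[1, ]
  axis <- axis / sqrt(sum(axis^2))
  structure(list(origin = origin, spacing = spacing, npts = npts,
                 channels = channels, box = box, groove_axis = axis,
                 out_of_box_penalty = ff$out_of_box_penalty,
                 receptor_subset = sel, receptor_set = rset,
                 ff_checksum = ff$table_checksum),
            class = "grid_maps")
}

# interpolate all channels at arbitrary points; returns matrix + inside
# column
.flatten_channels <- function(maps) {
  lapply(maps$channels, as.numeric)
}

.interp_channels <- function(maps, pts, flat = NULL) {
  if (is.null(flat)) flat <- .flatten_channels(maps)
  trilinear_cpp(flat, as.integer(maps$npts), maps$origin, maps$spacing,
                as.matrix(pts))
}

# combine per-atom channel values into receptor-ligand terms for a typed
# ligand set; `vals` must have the 7 channel columns (+ optional inside)
.combine_channels <- function(vals, lset, maps_penalty, inside = NULL) {
  if (is.null(inside)) inside <- rep(1, nrow(vals))
  E_vw <- sum((vals[, 1] + vals[, 2]) * inside) +
    maps_penalty * sum(inside == 0)
  E_el <- sum(lset$charge * vals[, 3] * inside)
  E_hb <- sum(as.integer(lset$donor) * vals[, 4] * inside +
              as.integer(lset$acceptor) * vals[, 5] * inside)
  E_hp <- sum(as.integer(lset$apolar) * vals[, 6] * inside)
  list(E_vw = E_vw, E_el = E_el, E_hb = E_hb, E_hp = E_hp,
       burial = vals[, 7] * inside, n_outside = sum(inside == 0))
}

#' Receptor--ligand energy from the grid maps
#'
#' Interpolates each channel trilinearly at every ligand atom and combines
#' them by atom type (charge weights the electrostatic channel, donors and
#' acceptors read the hydrogen-bond channels, apolar atoms the hydrophobic
#' channel). Atoms outside the box receive the out-of-box penalty.
#' Intra-ligand terms are not included.
#'
#' @param maps `grid_maps`.
#' @param ligand A `peptide_conformation` (or an `atom_set`).
#' @param ff Force field.
#' @return An `energy_breakdown` holding the receptor--ligand part
#'   (`E_vw`, `E_el`, `E_hb`, `E_hp`), with per-atom burial counts and the
#'   outside-atom count as attributes.
#' @export
grid_energy <- function(maps, ligand, ff = default_forcefield()) {
  lset <- if (inherits(ligand, "atom_set")) ligand else
    .conformation_to_set(ligand, ff)
  vals <- .interp_channels(maps, lset$xyz)
  parts <- .combine_channels(vals[, 1:7, drop = FALSE], lset,
                             maps$out_of_box_penalty, inside = vals[, 8])
  b <- energy_breakdown(E_vw = parts$E_vw, E_el = parts$E_el,
                        E_hb = parts$E_hb, E_hp = parts$E_hp)
  attr(b, "burial") <- parts$burial
  attr(b, "n_outside") <- parts$n_outside
  b
}

#' Direct (grid-free) receptor--ligand energy
#'
#' Evaluates the same receptor-field terms as [grid_energy()] exactly at
#' the ligand atom positions, without interpolation. This is the
#' reference the grid approximates; the two agree to interpolation error
#' inside the box.
#'
#' @inheritParams grid_energy
#' @return An `energy_breakdown` (receptor--ligand part).
#' @export
direct_receptor_energy <- function(maps, ligand, ff = default_forcefield()) {
  lset <- if (inherits(ligand, "atom_set")) ligand else
    .conformation_to_set(ligand, ff)
  r <- maps$receptor_set
  fld <- receptor_field_cpp(lset$xyz, r$xyz, r$cls, r$charge,
                            as.integer(r$donor), as.integer(r$donp),
                            as.integer(r$acceptor), as.integer(r$apolar),
                            .ff_cpp(ff))
  parts <- .combine_channels(fld, lset, maps$out_of_box_penalty)
  b <- energy_breakdown(E_vw = parts$E_vw, E_el = parts$E_el,
                        E_hb = parts$E_hb, E_hp = parts$E_hp)
  attr(b, "burial") <- parts$burial
  b
}
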