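# Energy terms and the two weighted scoring equations.

#' Construct a typed atom set
#'
#' Bundles coordinates with force-field typing so the pairwise energy
#' routines can be called on arbitrary atom selections.
#'
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @param resid Three-letter residue code per atom.
#' @param name PDB atom name per atom.
#' @param ff Force field.
#' @return list of class `atom_set` with `xyz`, typing columns and
#'   resolved donor-parent indices (0 when the antecedent is absent).
#' @export
atom_set <- function(xyz, resid, name, ff = default_forcefield()) {
  xyz <- as.matrix(xyz)
  resid <- rep(resid, length.out = nrow(xyz))
  name <- rep(name, length.out = nrow(xyz))
  ty <- type_atoms(resid, name, ff)
  donp <- integer(nrow(xyz))
  # donor antecedent must be the same residue instance; approximate by
  # nearest atom of that name within 2 A
  for (i in which(ty$donor)) {
    w <- which(name == ty$donor_parent[i] & resid == resid[i])
    if (length(w)) {
      d <- sqrt(colSums((t(xyz[w, , drop = FALSE]) - xyz[i, ])^2))
      if (min(d) < 2.0) donp[i] <- w[which.min(d)]
    }
  }
  structure(list(xyz = xyz, resid = resid, name = name, cls = ty$cls,
                 charge = ty$charge, donor = ty$donor, donp = donp,
                 acceptor = ty$acceptor, apolar = ty$apolar),
            class = "atom_set")
}

.atoms_df_to_set <- function(df, ff = default_forcefield()) {
  atom_set(as.matrix(df[, c("x", "y", "z")]), df$resid, df$elety, ff)
}

.conformation_to_set <- function(p, ff = default_forcefield()) {
  s <- atom_set(p$coords, p$atoms$code, p$atoms$name, ff)
  s$charge <- .add_terminal_charges(p, s$charge)
  s
}

# free peptides carry ionized termini (NH3+ / COO-); receptor chains are
# typed neutral
.add_terminal_charges <- function(p, charge) {
  nterm <- which(p$atoms$residue_index == 1L & p$atoms$name == "N")
  cterm <- which(p$atoms$residue_index == p$nres & p$atoms$name == "O")
  charge[nterm] <- charge[nterm] + 0.7
  charge[cterm] <- charge[cterm] - 0.7
  charge
}

# run the pairwise kernel on the union of two sets, keeping cross terms
# only (within-set pairs are marked excluded)
.cross_terms <- function(a, b, ff) {
  na <- nrow(a$xyz); nb <- nrow(b$xyz)
  xyz <- rbind(a$xyz, b$xyz)
  excl <- matrix(TRUE, na + nb, na + nb)
  excl[seq_len(na), na + seq_len(nb)] <- FALSE
  excl[na + seq_len(nb), seq_len(na)] <- FALSE
  donp <- c(ifelse(a$donp > 0, a$donp, 0L),
            ifelse(b$donp > 0, b$donp + na, 0L))
  intra_terms_cpp(xyz, c(a$cls, b$cls), c(a$charge, b$charge),
                  as.integer(c(a$donor, b$donor)), as.integer(donp),
                  as.integer(c(a$acceptor, b$acceptor)), excl, .ff_cpp(ff))
}

#' Van der Waals interaction energy between two atom sets
#'
#' Sum of 6-12 Lennard-Jones terms over cross pairs within the nonbonded
#' cutoff (switched smoothly to zero over the last Angstrom). Pair
#' energies are capped at +100 kcal/mol so steric clashes stay finite.
#'
#' @param a,b `atom_set` objects.
#' @param ff Force field.
#' @return Energy in kcal/mol.
#' @export
vdw_energy <- function(a, b, ff = default_forcefield()) {
  .cross_terms(a, b, ff)$vw
}

#' Electrostatic energy with distance-dependent dielectric
#'
#' Coulomb sum over cross pairs with epsilon = 4r, i.e. pair energy
#' k q1 q2 / (4 r^2), switched to zero at the nonbonded cutoff and capped
#' near clashes.
#'
#' @inheritParams vdw_energy
#' @return Energy in kcal/mol.
#' @export
electrostatic_energy <- function(a, b, ff = default_forcefield()) {
  .cross_terms(a, b, ff)$el
}

#' Hydrogen-bond energy between donors and acceptors
#'
#' Distance well with its minimum at the optimum donor--acceptor
#' separation, identically zero beyond the 3.65 A cutoff (smoothed over
#' the final 0.15 A so the term is continuous), modulated by a donor-side
#' angular factor when the donor antecedent is available.
#'
#' @inheritParams vdw_energy
#' @return Energy in kcal/mol (negative is favourable).
#' @export
hbond_energy <- function(a, b, ff = default_forcefield()) {
  .cross_terms(a, b, ff)$hb
}

#' Hydrophobic contact energy
#'
#' Favourable contact term between apolar atom pairs: full strength up to
#' 3.50 A, decaying linearly to zero at the 4.50 A van der Waals contact
#' cutoff. Pairs involving a polar atom contribute nothing.
#'
#' @inheritParams vdw_energy
#' @return Energy in kcal/mol (<= 0).
#' @export
hydrophobic_energy <- function(a, b, ff = default_forcefield()) {
  ia <- which(a$apolar); ib <- which(b$apolar)
  if (!length(ia) || !length(ib)) return(0)
  A <- a$xyz[ia, , drop = FALSE]; B <- b$xyz[ib, , drop = FALSE]
  d <- sqrt(outer(rowSums(A^2), rep(1, nrow(B))) +
            outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B))
  full <- ff$hp_full; cut <- ff$vdw_contact_cutoff
  e <- ifelse(d <= full, -ff$hp_strength,
              ifelse(d < cut, -ff$hp_strength * (cut - d) / (cut - full), 0))
  sum(e)
}

#' Solvent-accessible surface area
#'
#' Shrake-Rupley numeric SASA with a golden-spiral point set (960 points
#' per atom by default) and a 1.4 A probe.
#'
#' @param a An `atom_set`.
#' @param ff Force field (atom radii come from its class table).
#' @param subset Optional atom indices to report (all by default); every
#'   atom of `a` still occludes.
#' @param n_points Sphere sample points per atom.
#' @return Numeric vector of per-atom areas (A^2).
#' @export
sasa <- function(a, ff = default_forcefield(), subset = NULL,
                 n_points = ff$sasa_points) {
  if (is.null(subset)) subset <- seq_len(nrow(a$xyz))
  rad <- ff$r0[a$cls]
  sasa_cpp(a$xyz, rad, ff$sasa_probe, as.integer(n_points),
           as.integer(subset))
}

#' Surface-based solvation energy
#'
#' Sum over atoms of the atomic solvation parameter times the
#' solvent-accessible surface area of the atom within the given set.
#'
#' @inheritParams sasa
#' @return Energy in kcal/mol.
#' @export
solvation_energy <- function(a, ff = default_forcefield(),
                             n_points = ff$sasa_points) {
  ar <- sasa(a, ff, n_points = n_points)
  sum(ff$sigma[a$cls] * ar)
}

#' Side-chain configurational entropy penalty
#'
#' For each ligand residue, the per-residue entropy maximum scaled by the
#' buried fraction of its side chain: 1 - SASA(in complex)/SASA(ligand
#' alone), clamped to [0, 1]. Glycine (no side chain) and fully exposed
#' side chains contribute zero.
#'
#' @param ligand A `peptide_conformation`.
#' @param receptor An `atom_set` (or atoms data.frame) providing the
#'   burying environment.
#' @param ff Force field.
#' @param n_points SASA sampling density.
#' @return Penalty in kcal/mol (>= 0).
#' @export
entropy_term <- function(ligand, receptor, ff = default_forcefield(),
                         n_points = ff$sasa_points) {
  if (is.data.frame(receptor)) receptor <- .atoms_df_to_set(receptor, ff)
  lset <- .conformation_to_set(ligand, ff)
  side <- which(!(ligand$atoms$name %in% c("N", "CA", "C", "O")))
  if (!length(side)) return(0)
  free_a <- sasa(lset, ff, subset = side, n_points = n_points)
  comb <- atom_set(rbind(lset$xyz, receptor$xyz),
                   c(lset$resid, receptor$resid),
                   c(lset$name, receptor$name), ff)
  comp_a <- sasa(comb, ff, subset = side, n_points = n_points)
  res <- ligand$atoms$residue_index[side]
  e <- 0
  for (r in unique(res)) {
    w <- res == r
    fa <- sum(free_a[w]); ca <- sum(comp_a[w])
    bf <- if (fa > 1e-9) min(1, max(0, 1 - ca / fa)) else 0
    smax <- ff$entropy_max[ligand$parent_codes[r]]
    if (is.na(smax)) smax <- 0
    e <- e + smax * bf
  }
  unname(e)
}

#' Energy breakdown container
#'
#' Holds the named terms of the two scoring equations (kcal/mol):
#' `E_vw` (van der Waals), `E_en` (side-chain entropy), `E_el`
#' (electrostatics entering the docking score), `E_hb` (hydrogen bonds),
#' `E_hp` (hydrophobic contacts), `E_solv` (surface solvation), `E_tors`
#' (torsion strain) and `E_elec` (electrostatics entering the refinement
#' score).
#'
#' @param E_vw,E_en,E_el,E_hb,E_hp,E_solv,E_tors,E_elec Term values.
#' @return list of class `energy_breakdown` (with `total` initially NA).
#' @export
energy_breakdown <- function(E_vw = 0, E_en = 0, E_el = 0, E_hb = 0,
                             E_hp = 0, E_solv = 0, E_tors = 0, E_elec = 0) {
  structure(list(E_vw = E_vw, E_en = E_en, E_el = E_el, E_hb = E_hb,
                 E_hp = E_hp, E_solv = E_solv, E_tors = E_tors,
                 E_elec = E_elec, total = NA_real_),
            class = "energy_breakdown")
}

#' Docking-stage score
#'
#' `E = E_vw + E_en + w_el E_el + w_hb E_hb + w_hp E_hp + w_solv E_solv`
#' with default weights 2.16, 2.53, 4.35 and 0.20.
#'
#' @param b An `energy_breakdown`.
#' @param w Weights from [scoring_weights()].
#' @return The weighted total (kcal/mol).
#' @export
docking_score <- function(b, w = scoring_weights()) {
  b$E_vw + b$E_en + w$w_el * b$E_el + w$w_hb * b$E_hb + w$w_hp * b$E_hp +
    w$w_solv * b$E_solv
}

#' Refinement-stage score
#'
#' Unweighted sum `E_vw + E_hb + E_tors + E_elec + E_solv + E_en` used
#' during interface refinement.
#'
#' @param b An `energy_breakdown`.
#' @return The total (kcal/mol).
#' @export
refinement_score <- function(b) {
  b$E_vw + b$E_hb + b$E_tors + b$E_elec + b$E_solv + b$E_en
}

#' @export
print.energy_breakdown <- function(x, ...) {
  terms <- unlist(x[c("E_vw", "E_en", "E_el", "E_hb", "E_hp", "E_solv",
                      "E_tors", "E_elec")])
  cat("energy breakdown (kcal/mol):\n")
  print(round(terms, 3))
  if (!is.na(x$total)) cat("total:", round(x$total, 3), "\n")
  invisible(x)
}

# torsion strain of a ligand conformation: 3-fold barrier on rotatable
# side-chain chi angles plus a stiff 2-fold term keeping omega trans
.torsion_energy <- function(p, ff) {
  chi <- grepl("^chi", p$torsion_kind) & p$parent_codes[p$torsion_res] != "PRO"
  om <- p$torsion_kind == "omega" & p$torsion_res > 1
  v <- p$torsions
  sum(ff$torsion_v3 / 2 * (1 + cos(3 * v[chi] * pi / 180))) +
    sum(ff$torsion_vomega / 2 * (1 - cos((v[om] - 180) * pi / 180)))
}
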