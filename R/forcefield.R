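#' Default force-field parameter set
#'
#' Loads the versioned united-atom parameter table shipped with the package
#' and assembles the full parameter list used by every energy routine:
#' per-class Lennard-Jones radii and well depths, atomic solvation
#' parameters, hydrogen-bond geometry (heavy-atom donor--acceptor well,
#' optimum 2.90 A, hard cutoff 3.65 A), the 4.50 A van der Waals contact
#' cutoff, the distance-dependent dielectric (epsilon = 4r), per-residue
#' side-chain entropy maxima and torsion barrier heights.
#'
#' The model is a united-atom treatment: nonpolar hydrogens are implicit in
#' their heavy atoms and polar hydrogens are represented through heavy-atom
#' donor typing with an antecedent-based angular factor. Pair energies are
#' capped at +100 kcal/mol (`clash_cap`) so steric clashes stay finite; the
#' intermolecular steric wall used for grid fields additionally saturates
#' smoothly above `sat_onset` kcal/mol so that the maps interpolate stably
#' at 1 A spacing.
#'
#' @param file Optional path to an alternative parameter table (same
#'   columns as the shipped `forcefield_v1.tsv`).
#' @return A list of class `groove_forcefield`; see the package vignette
#'   for the meaning and units of every entry.
#' @export
default_forcefield <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "forcefield_v1.tsv", package = "grooveDock")
  }
  tab <- utils::read.table(file, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  ff <- list(
    table_file = file,
    table_checksum = ff_checksum(file),
    classes = tab$class,
    r0 = as.numeric(tab$r0),
    eps = as.numeric(tab$eps),
    sigma = as.numeric(tab$sigma),
    apolar_class = as.integer(tab$apolar),
    # cutoffs and global constants
    nb_cutoff = 8.0,           # A, nonbonded cutoff (switched over last 1 A)
    switch_width = 1.0,        # A
    vdw_contact_cutoff = 4.50, # A, hydrophobic / contact definition
    hb_cutoff = 3.65,          # A, maximum donor-acceptor distance
    hb_switch = 3.50,          # A, start of the smoothing window
    hb_d0 = 2.90,              # A, optimum donor-acceptor distance
    hb_depth = 2.0,            # kcal/mol
    hp_full = 3.50,            # A, full-strength hydrophobic contact
    hp_strength = 0.05,        # kcal/mol per apolar pair in contact
    coulomb_k = 332.06,        # kcal A / (mol e^2)
    dielectric = "4r",
    clash_floor = 0.1,         # A
    clash_cap = 100,           # kcal/mol per pair
    elec_cap = 2.0,            # kcal/mol cap on a single Coulomb pair
    sat_onset = 2.5,           # kcal/mol, grid steric wall saturation
    sat_cap = 6.0,             # kcal/mol
    probe_r0 = 2.00,           # generic carbon probe for the steric field
    probe_eps = 0.10,
    burial_radius = 6.0,       # A, neighbour count radius for burial
    burial_sat = 25,           # neighbour count treated as fully buried
    sasa_probe = 1.4,          # A, solvent probe radius
    sasa_points = 960,         # sphere sample points per atom
    torsion_v3 = 0.6,          # kcal/mol, 3-fold side-chain barrier
    torsion_vomega = 10.0,     # kcal/mol, 2-fold peptide-bond barrier
    out_of_box_penalty = 10.0  # kcal/mol per atom outside the grid
  )
  ff$entropy_max <- c(
    ALA = 0, ARG = 2.1, ASN = 1.2, ASP = 1.0, CYS = 0.9, GLN = 1.7,
    GLU = 1.7, GLY = 0, HIS = 1.0, ILE = 0.9, LEU = 0.8, LYS = 2.0,
    MET = 1.6, PHE = 0.9, PRO = 0, SER = 1.0, THR = 1.0, TRP = 1.4,
    TYR = 1.4, VAL = 0.5)
  class(ff) <- "groove_forcefield"
  ff
}

ff_checksum <- function(file) {
  txt <- readLines(file, warn = FALSE)
  # small deterministic text checksum; no external digest dependency
  sum(as.numeric(utf8ToInt(paste(txt, collapse = "\n"))) *
        (seq_along(utf8ToInt(paste(txt, collapse = "\n"))) %% 97 + 1)) %% 1e9
}

#' Scoring weights of the docking energy function
#'
#' The docking-stage total is
#' `E = E_vw + E_en + w_el * E_el + w_hb * E_hb + w_hp * E_hp + w_solv * E_solv`
#' with the default weights 2.16 (electrostatic/solvation electrostatics),
#' 2.53 (hydrogen bonding), 4.35 (hydrophobic) and 0.20 (surface
#' solvation).
#'
#' @param w_el,w_hb,w_hp,w_solv Dimensionless term weights.
#' @return A list of class `groove_weights`.
#' @export
scoring_weights <- function(w_el = 2.16, w_hb = 2.53, w_hp = 4.35,
                            w_solv = 0.20) {
  structure(list(w_el = w_el, w_hb = w_hb, w_hp = w_hp, w_solv = w_solv),
            class = "groove_weights")
}

# --- atom typing -----------------------------------------------------------

# residue+atom -> partial charge (e); anything absent is neutral
.charge_table <- local({
  bb <- c(N = -0.40, CA = 0.30, C = 0.60, O = -0.50, OXT = -0.50)
  side <- list(
    SER = c(CB = 0.30, OG = -0.30),
    THR = c(CB = 0.30, OG1 = -0.30),
    TYR = c(CZ = 0.30, OH = -0.30),
    CYS = c(CB = 0.10, SG = -0.10),
    ASP = c(CG = 0.20, OD1 = -0.45, OD2 = -0.45),
    GLU = c(CD = 0.20, OE1 = -0.45, OE2 = -0.45),
    ASN = c(CG = 0.55, OD1 = -0.55),
    GLN = c(CD = 0.55, OE1 = -0.55),
    LYS = c(NZ = 0.70),
    ARG = c(NE = 0.15, CZ = 0.15, NH1 = 0.20, NH2 = 0.20))
  list(backbone = bb, side = side)
})

# heavy-atom donors with the antecedent used for the angular factor
.donor_table <- list(
  "*" = c(N = "CA"),
  SER = c(OG = "CB"), THR = c(OG1 = "CB"), TYR = c(OH = "CZ"),
  CYS = c(SG = "CB"), LYS = c(NZ = "CE"),
  ARG = c(NE = "CD", NH1 = "CZ", NH2 = "CZ"),
  ASN = c(ND2 = "CG"), GLN = c(NE2 = "CD"),
  HIS = c(ND1 = "CG", NE2 = "CD2"), TRP = c(NE1 = "CD1"))

.acceptor_names <- list(
  "*" = c("O", "OXT"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH",
  HIS = c("ND1", "NE2"))

.class_of_atom <- function(res, name) {
  if (name %in% c("N")) return("NAM")
  if (name %in% c("C")) return("CCO")
  if (name %in% c("O", "OXT")) return(if (name == "OXT") "ONEG" else "OCO")
  if (name == "CA") return("C3")
  aromatic <- list(
    PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    TYR = c("CG", "CD1", "CD2", "CE1", "CE2"),
    TRP = c("CG", "CD1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
    HIS = c("CG", "CD2", "CE1"))
  if (!is.null(aromatic[[res]]) && name %in% aromatic[[res]]) return("CAR")
  if (res == "TYR" && name == "CZ") return("CAR")
  if (res %in% c("ASP", "ASN") && name == "CG") return("CCO")
  if (res %in% c("GLU", "GLN") && name == "CD") return("CCO")
  if (res == "ARG" && name == "CZ") return("CCO")
  if (name %in% c("SG", "SD")) return("S")
  if (name %in% c("OG", "OG1", "OH")) return("OOH")
  if (name %in% c("OD1", "OD2", "OE1", "OE2"))
    return(if (res %in% c("ASP", "GLU")) "ONEG" else "OCO")
  if (name %in% c("ND1", "ND2", "NE", "NE1", "NE2", "NH1", "NH2", "NZ")) {
    if (res == "LYS" && name == "NZ") return("NPOS")
    if (res == "ARG" && name %in% c("NE", "NH1", "NH2")) return("NPOS")
    return("NAM")
  }
  "C3"
}

#' Assign force-field atom types
#'
#' Maps residue codes and PDB atom names to atom classes, partial charges,
#' hydrogen-bond donor/acceptor flags (with the donor antecedent used for
#' the angular factor) and apolarity. Unknown names fall back to a generic
#' aliphatic carbon.
#'
#' @param resid Character vector of three-letter residue codes.
#' @param name Character vector of atom names, same length.
#' @param ff Force field from [default_forcefield()].
#' @return A data.frame with columns `cls` (class index into `ff$classes`),
#'   `charge`, `donor`, `acceptor`, `apolar` and `donor_parent` (atom name
#'   or NA).
#' @export
type_atoms <- function(resid, name, ff = default_forcefield()) {
  n <- length(name)
  cls_lab <- character(n)
  charge <- numeric(n)
  donor <- logical(n)
  acceptor <- logical(n)
  parent <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    res <- resid[i]
    at <- name[i]
    cls_lab[i] <- .class_of_atom(res, at)
    ch <- .charge_table$backbone[at]
    if (is.na(ch)) ch <- .charge_table$side[[res]][at]
    charge[i] <- if (length(ch) && !is.na(ch)) ch else 0
    dt <- .donor_table[["*"]][at]
    if (is.na(dt) && !is.null(.donor_table[[res]])) dt <- .donor_table[[res]][at]
    if (length(dt) && !is.na(dt)) {
      donor[i] <- TRUE
      parent[i] <- unname(dt)
    }
    accs <- c(.acceptor_names[["*"]], .acceptor_names[[res]])
    acceptor[i] <- at %in% accs
  }
  cls <- match(cls_lab, ff$classes)
  cls[is.na(cls)] <- match("C3", ff$classes)
  data.frame(cls = cls, charge = charge, donor = donor, acceptor = acceptor,
             apolar = ff$apolar_class[cls] == 1L,
             donor_parent = parent, stringsAsFactors = FALSE)
}

# flat list view of ff consumed by the C++ kernels
.ff_cpp <- function(ff) {
  list(r0 = ff$r0, eps = ff$eps,
       nb_cutoff = ff$nb_cutoff, switch_width = ff$switch_width,
       clash_cap = ff$clash_cap, elec_cap = ff$elec_cap,
       coulomb_k = ff$coulomb_k,
       hb_d0 = ff$hb_d0, hb_depth = ff$hb_depth, hb_cutoff = ff$hb_cutoff,
       hb_switch = ff$hb_switch, hp_full = ff$hp_full,
       vdw_contact_cutoff = ff$vdw_contact_cutoff,
       hp_strength = ff$hp_strength, sat_onset = ff$sat_onset,
       sat_cap = ff$sat_cap, probe_r0 = ff$probe_r0,
       probe_eps = ff$probe_eps, burial_radius = ff$burial_radius)
}
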