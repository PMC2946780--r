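# Internal-coordinate peptide model: residue z-matrix templates, the
# peptide_conformation class, Cartesian rebuilds and torsion measurement.

# backbone ideal geometry (A, degrees)
.BB <- list(
  b_N_CA = 1.458, b_CA_C = 1.525, b_C_N = 1.329, b_C_O = 1.231,
  b_CA_CB = 1.530,
  a_C_N_CA = 121.7, a_N_CA_C = 111.2, a_CA_C_N = 116.2, a_CA_C_O = 120.8,
  a_N_CA_CB = 110.5,
  # improper dihedral CB-CA-N-C fixing L-chirality (sign verified against
  # crystallographic residues)
  d_CB = -122.6)

# side-chain rows: name, parents i/j/k (atom names in the same residue),
# bond (A), angle (deg), torsion label (x1..x4 or NA for fixed), offset (deg)
.sc_row <- function(name, i, j, k, b, a, tor = NA, off = 0) {
  data.frame(name = name, i = i, j = j, k = k, bond = b, angle = a,
             tor = tor, off = off, stringsAsFactors = FALSE)
}

.SIDE_TEMPLATES <- local({
  phe <- rbind(
    .sc_row("CG", "CB", "CA", "N", 1.510, 113.8, "x1"),
    .sc_row("CD1", "CG", "CB", "CA", 1.390, 120.8, "x2"),
    .sc_row("CD2", "CG", "CB", "CA", 1.390, 120.8, "x2", 180),
    .sc_row("CE1", "CD1", "CG", "CB", 1.390, 120.8, NA, 180),
    .sc_row("CE2", "CD2", "CG", "CB", 1.390, 120.8, NA, 180),
    .sc_row("CZ", "CE1", "CD1", "CG", 1.390, 120.0, NA, 0))
  list(
    GLY = NULL, ALA = NULL,
    SER = .sc_row("OG", "CB", "CA", "N", 1.417, 110.8, "x1"),
    CYS = .sc_row("SG", "CB", "CA", "N", 1.808, 114.4, "x1"),
    THR = rbind(.sc_row("OG1", "CB", "CA", "N", 1.433, 109.6, "x1"),
                .sc_row("CG2", "CB", "CA", "N", 1.521, 110.5, "x1", -120)),
    VAL = rbind(.sc_row("CG1", "CB", "CA", "N", 1.527, 110.5, "x1"),
                .sc_row("CG2", "CB", "CA", "N", 1.527, 110.5, "x1", 120)),
    LEU = rbind(.sc_row("CG", "CB", "CA", "N", 1.530, 116.3, "x1"),
                .sc_row("CD1", "CG", "CB", "CA", 1.521, 110.7, "x2"),
                .sc_row("CD2", "CG", "CB", "CA", 1.521, 110.7, "x2", 120)),
    ILE = rbind(.sc_row("CG1", "CB", "CA", "N", 1.530, 110.4, "x1"),
                .sc_row("CG2", "CB", "CA", "N", 1.521, 110.5, "x1", -120),
                .sc_row("CD1", "CG1", "CB", "CA", 1.513, 113.9, "x2")),
    MET = rbind(.sc_row("CG", "CB", "CA", "N", 1.520, 114.1, "x1"),
                .sc_row("SD", "CG", "CB", "CA", 1.803, 112.7, "x2"),
                .sc_row("CE", "SD", "CG", "CB", 1.791, 100.9, "x3")),
    PRO = rbind(.sc_row("CG", "CB", "CA", "N", 1.495, 104.5, NA, 30),
                .sc_row("CD", "CG", "CB", "CA", 1.507, 106.1, NA, -35)),
    PHE = phe,
    TYR = rbind(phe, .sc_row("OH", "CZ", "CE1", "CD1", 1.376, 119.9, NA, 180)),
    TRP = rbind(.sc_row("CG", "CB", "CA", "N", 1.498, 114.6, "x1"),
                .sc_row("CD1", "CG", "CB", "CA", 1.365, 126.9, "x2"),
                .sc_row("CD2", "CG", "CB", "CA", 1.433, 126.7, "x2", 180),
                .sc_row("NE1", "CD1", "CG", "CB", 1.374, 110.2, NA, 180),
                .sc_row("CE2", "CD2", "CG", "CB", 1.409, 107.2, NA, 180),
                .sc_row("CE3", "CD2", "CG", "CB", 1.398, 133.9, NA, 0),
                .sc_row("CZ2", "CE2", "CD2", "CG", 1.394, 122.4, NA, 180),
                .sc_row("CZ3", "CE3", "CD2", "CG", 1.382, 118.6, NA, 180),
                .sc_row("CH2", "CZ2", "CE2", "CD2", 1.368, 117.5, NA, 0)),
    ASP = rbind(.sc_row("CG", "CB", "CA", "N", 1.516, 112.6, "x1"),
                .sc_row("OD1", "CG", "CB", "CA", 1.249, 118.4, "x2"),
                .sc_row("OD2", "CG", "CB", "CA", 1.249, 118.4, "x2", 180)),
    ASN = rbind(.sc_row("CG", "CB", "CA", "N", 1.516, 112.6, "x1"),
                .sc_row("OD1", "CG", "CB", "CA", 1.231, 120.8, "x2"),
                .sc_row("ND2", "CG", "CB", "CA", 1.328, 116.4, "x2", 180)),
    GLU = rbind(.sc_row("CG", "CB", "CA", "N", 1.520, 114.1, "x1"),
                .sc_row("CD", "CG", "CB", "CA", 1.516, 112.6, "x2"),
                .sc_row("OE1", "CD", "CG", "CB", 1.249, 118.4, "x3"),
                .sc_row("OE2", "CD", "CG", "CB", 1.249, 118.4, "x3", 180)),
    GLN = rbind(.sc_row("CG", "CB", "CA", "N", 1.520, 114.1, "x1"),
                .sc_row("CD", "CG", "CB", "CA", 1.516, 112.6, "x2"),
                .sc_row("OE1", "CD", "CG", "CB", 1.231, 120.8, "x3"),
                .sc_row("NE2", "CD", "CG", "CB", 1.328, 116.4, "x3", 180)),
    LYS = rbind(.sc_row("CG", "CB", "CA", "N", 1.520, 114.1, "x1"),
                .sc_row("CD", "CG", "CB", "CA", 1.520, 111.3, "x2"),
                .sc_row("CE", "CD", "CG", "CB", 1.520, 111.3, "x3"),
                .sc_row("NZ", "CE", "CD", "CG", 1.489, 111.5, "x4")),
    ARG = rbind(.sc_row("CG", "CB", "CA", "N", 1.520, 114.1, "x1"),
                .sc_row("CD", "CG", "CB", "CA", 1.520, 111.3, "x2"),
                .sc_row("NE", "CD", "CG", "CB", 1.460, 112.0, "x3"),
                .sc_row("CZ", "NE", "CD", "CG", 1.330, 124.2, "x4"),
                .sc_row("NH1", "CZ", "NE", "CD", 1.326, 120.0, NA, 0),
                .sc_row("NH2", "CZ", "NE", "CD", 1.326, 120.0, NA, 180)),
    HIS = rbind(.sc_row("CG", "CB", "CA", "N", 1.497, 113.8, "x1"),
                .sc_row("ND1", "CG", "CB", "CA", 1.378, 122.7, "x2"),
                .sc_row("CD2", "CG", "CB", "CA", 1.354, 131.0, "x2", 180),
                .sc_row("CE1", "ND1", "CG", "CB", 1.320, 109.3, NA, 180),
                .sc_row("NE2", "CD2", "CG", "CB", 1.374, 107.2, NA, 180)))
})

# chemical analogue ("X") -> nearest standard parent residue
.ANALOGUE_PARENTS <- c(
  MSE = "MET", SEP = "SER", TPO = "THR", PTR = "TYR", CSO = "CYS",
  MLY = "LYS", ALY = "LYS", ORN = "LYS", HYP = "PRO", ABA = "ALA",
  AIB = "ALA", NLE = "LEU", NVA = "VAL", SAR = "GLY", DAL = "ALA",
  PCA = "GLU", CME = "CYS", KCX = "LYS", LLP = "LYS", M3L = "LYS")

#' Map a residue code to its standard parent
#'
#' Standard residues map to themselves; known chemical analogues map to the
#' closest standard residue (used for parameter assignment while the
#' original name is kept for output); anything else falls back to alanine
#' with an analogue flag.
#'
#' @param code Three-letter residue code(s).
#' @return data.frame with `code`, `parent_code`, `is_analogue`.
#' @export
map_analogue <- function(code) {
  std <- names(.SIDE_TEMPLATES)
  parent <- ifelse(code %in% std, code,
                   ifelse(code %in% names(.ANALOGUE_PARENTS),
                          .ANALOGUE_PARENTS[code], "ALA"))
  data.frame(code = code, parent_code = unname(parent),
             is_analogue = !(code %in% std), stringsAsFactors = FALSE)
}

# Build the z-matrix for a peptide sequence (3-letter parent codes).
# Torsion vector layout: per residue phi, psi, omega, chi1..chik
# (phi of residue 1 and omega of residue 1 are inert placeholders).
.peptide_template <- function(codes) {
  nres <- length(codes)
  tor_names <- character(0)
  tor_res <- integer(0)
  tor_kind <- character(0)
  add_tor <- function(kind, res) {
    tor_names <<- c(tor_names, paste0(kind, "_", res))
    tor_res <<- c(tor_res, res)
    tor_kind <<- c(tor_kind, kind)
    length(tor_names)
  }
  atoms <- list()   # rows: name, res, code
  zi <- zj <- zk <- ztor <- integer(0)
  zb <- za <- zd <- numeric(0)
  idx <- new.env(parent = emptyenv())
  key <- function(res, name) paste0(res, ".", name)
  add_atom <- function(name, res, code, i, j, k, b, a, d, t) {
    atoms[[length(atoms) + 1L]] <<- list(name = name, res = res, code = code)
    n <- length(atoms)
    assign(key(res, name), n, envir = idx)
    zi <<- c(zi, i); zj <<- c(zj, j); zk <<- c(zk, k)
    zb <<- c(zb, b); za <<- c(za, a); zd <<- c(zd, d)
    ztor <<- c(ztor, t)
    n
  }
  gi <- function(res, name) get(key(res, name), envir = idx)
  tidx <- list()  # per residue: named torsion indices
  for (r in seq_len(nres)) {
    code <- codes[r]
    ti <- c(phi = add_tor("phi", r), psi = add_tor("psi", r),
            omega = add_tor("omega", r))
    if (r == 1L) {
      add_atom("N", 1L, code, 0L, 0L, 0L, 0, 0, 0, 0L)
      add_atom("CA", 1L, code, gi(1, "N"), 0L, 0L, .BB$b_N_CA, 0, 0, 0L)
      add_atom("C", 1L, code, gi(1, "CA"), gi(1, "N"), 0L, .BB$b_CA_C,
               .BB$a_N_CA_C, 0, 0L)
    } else {
      pr <- r - 1L
      add_atom("N", r, code, gi(pr, "C"), gi(pr, "CA"), gi(pr, "N"),
               .BB$b_C_N, .BB$a_CA_C_N, 0, tidx[[pr]]["psi"])
      add_atom("CA", r, code, gi(r, "N"), gi(pr, "C"), gi(pr, "CA"),
               .BB$b_N_CA, .BB$a_C_N_CA, 0, ti["omega"])
      add_atom("C", r, code, gi(r, "CA"), gi(r, "N"), gi(pr, "C"),
               .BB$b_CA_C, .BB$a_N_CA_C, 0, ti["phi"])
    }
    # carbonyl O: dihedral O-C-CA-N = psi + 180
    add_atom("O", r, code, gi(r, "C"), gi(r, "CA"), gi(r, "N"),
             .BB$b_C_O, .BB$a_CA_C_O, 180, ti["psi"])
    if (code != "GLY") {
      add_atom("CB", r, code, gi(r, "CA"), gi(r, "N"), gi(r, "C"),
               .BB$b_CA_CB, .BB$a_N_CA_CB, .BB$d_CB, 0L)
      sc <- .SIDE_TEMPLATES[[code]]
      if (!is.null(sc)) {
        chis <- unique(stats::na.omit(sc$tor))
        for (x in sort(chis)) {
          rank <- as.integer(sub("x", "", x))
          ti[x] <- add_tor(paste0("chi", rank), r)
        }
        for (s in seq_len(nrow(sc))) {
          t <- 0L
          if (!is.na(sc$tor[s])) t <- ti[[sc$tor[s]]]
          add_atom(sc$name[s], r, code, gi(r, sc$i[s]), gi(r, sc$j[s]),
                   gi(r, sc$k[s]), sc$bond[s], sc$angle[s], sc$off[s], t)
        }
      }
    }
    tidx[[r]] <- ti
  }
  at <- data.frame(
    name = vapply(atoms, `[[`, "", "name"),
    residue_index = vapply(atoms, `[[`, 1L, "res"),
    code = vapply(atoms, `[[`, "", "code"),
    stringsAsFactors = FALSE)
  list(atoms = at, codes = codes,
       zmat = list(i = zi, j = zj, k = zk, bond = zb, angle = za,
                   dih0 = zd, tidx = ztor),
       torsion_names = tor_names, torsion_res = tor_res,
       torsion_kind = tor_kind, nres = nres)
}

#' Create a flexible peptide conformation
#'
#' Represents a peptide in internal coordinates: a torsion vector (phi,
#' psi, omega and side-chain chi angles per residue) plus a rigid-body
#' placement (rotation matrix and translation). Cartesian coordinates are
#' derived deterministically from these via ideal bond lengths and angles.
#' Chemical analogues are built with the geometry and parameters of their
#' standard parent residue while the original code is retained.
#'
#' @param sequence One-letter peptide sequence, or a character vector of
#'   three-letter codes (analogues allowed).
#' @param torsions Optional named torsion vector (degrees, in (-180, 180]);
#'   defaults to an extended backbone (phi -139, psi +135, omega 180) with
#'   chi = 180.
#' @param rotation 3x3 rigid-body rotation matrix.
#' @param translation Length-3 translation (Angstrom).
#' @return An object of class `peptide_conformation` with elements
#'   `sequence`, `codes`, `parent_codes`, `is_analogue`, `atoms`,
#'   `torsions`, `rotation`, `translation` and derived `coords`.
#' @export
peptide_conformation <- function(sequence, torsions = NULL,
                                 rotation = diag(3),
                                 translation = c(0, 0, 0)) {
  if (length(sequence) == 1L && !sequence %in% names(.SIDE_TEMPLATES)) {
    codes <- bio3d::aa123(strsplit(sequence, "")[[1]])
  } else {
    codes <- sequence
  }
  amap <- map_analogue(codes)
  tpl <- .peptide_template(amap$parent_code)
  one <- bio3d::aa321(amap$parent_code)
  tor <- .default_torsions(tpl)
  if (!is.null(torsions)) {
    if (is.null(names(torsions)) && length(torsions) == length(tor)) {
      tor[] <- torsions
    } else {
      shared <- intersect(names(torsions), names(tor))
      tor[shared] <- torsions[shared]
    }
  }
  p <- structure(list(
    sequence = paste(one, collapse = ""),
    codes = amap$code, parent_codes = amap$parent_code,
    is_analogue = amap$is_analogue,
    atoms = tpl$atoms, zmat = tpl$zmat,
    torsion_names = tpl$torsion_names, torsion_res = tpl$torsion_res,
    torsion_kind = tpl$torsion_kind, nres = tpl$nres,
    torsions = tor, rotation = rotation, translation = translation),
    class = "peptide_conformation")
  p$ca_idx <- which(p$atoms$name == "CA")
  rebuild_coords(p)
}

.default_torsions <- function(tpl) {
  tor <- numeric(length(tpl$torsion_names))
  names(tor) <- tpl$torsion_names
  tor[tpl$torsion_kind == "phi"] <- -139
  tor[tpl$torsion_kind == "psi"] <- 135
  tor[tpl$torsion_kind == "omega"] <- 180
  chi <- grepl("^chi", tpl$torsion_kind)
  tor[chi] <- 180
  # planar side chains sit near perpendicular, not anti
  planar2 <- chi & tpl$torsion_kind != "chi1" &
    tpl$codes[tpl$torsion_res] %in% c("PHE", "TYR", "TRP", "HIS", "ASP",
                                      "ASN")
  tor[planar2] <- 90
  tor
}

#' Rebuild Cartesian coordinates from internal coordinates
#'
#' @param p A `peptide_conformation`.
#' @return The conformation with `coords` recomputed from the current
#'   torsions and rigid-body placement.
#' @export
rebuild_coords <- function(p) {
  z <- p$zmat
  p$coords <- build_coords_cpp(z$i, z$j, z$k, z$bond, z$angle, z$dih0,
                               z$tidx, unname(p$torsions), p$rotation,
                               p$translation)
  p
}

#' @export
print.peptide_conformation <- function(x, ...) {
  cat("peptide_conformation:", x$sequence, sprintf("(%d residues, %d atoms)\n",
      x$nres, nrow(x$atoms)))
  invisible(x)
}

# --- geometry helpers ------------------------------------------------------

.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  nb2 <- sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2) / nb2
  ang <- -atan2(y, x) * 180 / pi  # IUPAC sign convention
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Measure backbone and side-chain torsions from coordinates
#'
#' Computes phi/psi/omega (and chi angles where the template defines them)
#' from a coordinate matrix matching the conformation's atom table. Used
#' when extracting a crystallographic peptide into the internal-coordinate
#' model.
#'
#' @param p A `peptide_conformation`.
#' @param coords Optional coordinate matrix (defaults to `p$coords`).
#' @return Named torsion vector (degrees).
#' @export
measure_torsions <- function(p, coords = NULL) {
  if (is.null(coords)) coords <- p$coords
  at <- p$atoms
  gi <- function(res, name) {
    w <- which(at$residue_index == res & at$name == name)
    if (length(w)) w[1] else NA_integer_
  }
  tor <- p$torsions
  for (t in seq_along(tor)) {
    res <- p$torsion_res[t]
    kind <- p$torsion_kind[t]
    q <- switch(kind,
      phi = if (res > 1) c(gi(res - 1, "C"), gi(res, "N"), gi(res, "CA"),
                           gi(res, "C")),
      psi = if (res < p$nres) c(gi(res, "N"), gi(res, "CA"), gi(res, "C"),
                                gi(res + 1, "N")) else
            c(gi(res, "N"), gi(res, "CA"), gi(res, "C"), gi(res, "O")),
      omega = if (res > 1) c(gi(res - 1, "CA"), gi(res - 1, "C"),
                             gi(res, "N"), gi(res, "CA")),
      NULL)
    if (is.null(q) && grepl("^chi", kind)) {
      rank <- as.integer(sub("chi", "", kind))
      chain <- .chi_chain(p$parent_codes[res])
      if (length(chain) >= rank + 3)
        q <- vapply(chain[rank:(rank + 3)], gi, 1L, res = res)
      q <- rev(q)
    }
    if (is.null(q) || anyNA(q)) next
    v <- .dihedral(coords[q[1], ], coords[q[2], ], coords[q[3], ],
                   coords[q[4], ])
    if (kind == "psi" && res == p$nres) v <- .wrap_angle(v + 180)
    tor[t] <- v
  }
  tor
}

# atom chain defining chi angles, listed from the tip inward is not needed;
# order: N, CA, CB, then successive side-chain axis atoms
.chi_chain <- function(code) {
  axis <- switch(code,
    SER = "OG", CYS = "SG", THR = "OG1", VAL = "CG1",
    LEU = c("CG", "CD1"), ILE = c("CG1", "CD1"),
    MET = c("CG", "SD", "CE"), PHE = c("CG", "CD1"), TYR = c("CG", "CD1"),
    TRP = c("CG", "CD1"), ASP = c("CG", "OD1"), ASN = c("CG", "OD1"),
    GLU = c("CG", "CD", "OE1"), GLN = c("CG", "CD", "OE1"),
    LYS = c("CG", "CD", "CE", "NZ"),
    ARG = c("CG", "CD", "NE", "CZ"), HIS = c("CG", "ND1"),
    NULL)
  if (is.null(axis)) return(character(0))
  rev(c(rev(axis), "CB", "CA", "N"))
}

.wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  ifelse(a <= -180, a + 360, a)
}

# rotation matrix about a unit axis
.rot_axis <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
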