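# Pairwise energy terms against independent brute-force oracles, and the
# two weighted scoring equations.

ff <- default_forcefield()

# two-apolar-carbon pair at a chosen separation
pair_sets <- function(r) {
  a <- atom_set(matrix(c(0, 0, 0), 1), "ALA", "CB", ff)
  b <- atom_set(matrix(c(r, 0, 0), 1), "ALA", "CB", ff)
  list(a = a, b = b)
}

# plain-R reimplementation of the pair formulas (oracle)
oracle_pairs <- function(a, b, ff) {
  sw <- function(r, on, off) {
    t <- pmin(1, pmax(0, (r - on) / (off - on)))
    1 - t^2 * (3 - 2 * t)
  }
  vw <- el <- hb <- hp <- 0
  for (i in seq_len(nrow(a$xyz))) for (j in seq_len(nrow(b$xyz))) {
    r <- sqrt(sum((a$xyz[i, ] - b$xyz[j, ])^2))
    if (r > ff$nb_cutoff) next
    s <- sw(r, ff$nb_cutoff - ff$switch_width, ff$nb_cutoff)
    R0 <- ff$r0[a$cls[i]] + ff$r0[b$cls[j]]
    e <- sqrt(ff$eps[a$cls[i]] * ff$eps[b$cls[j]]) *
      ((R0 / max(r, 0.1))^12 - 2 * (R0 / max(r, 0.1))^6)
    vw <- vw + min(e, ff$clash_cap) * s
    v <- ff$coulomb_k * a$charge[i] * b$charge[j] / (4 * max(r, 0.5)^2)
    el <- el + max(min(v, ff$elec_cap), -ff$elec_cap) * s
    if (a$apolar[i] && b$apolar[j] && r < ff$vdw_contact_cutoff) {
      hp <- hp + ifelse(r <= ff$hp_full, -ff$hp_strength,
                        -ff$hp_strength * (ff$vdw_contact_cutoff - r) /
                          (ff$vdw_contact_cutoff - ff$hp_full))
    }
  }
  list(vw = vw, el = el, hp = hp)
}

test_that("van der Waals term hits its minimum and cutoff exactly", {
  ps <- pair_sets(4.0)  # r = r0_i + r0_j for two C3 atoms
  expect_equal(vdw_energy(ps$a, ps$b), -sqrt(ff$eps[1] * ff$eps[1]),
               tolerance = 1e-10)
  far <- pair_sets(50)
  expect_equal(vdw_energy(far$a, far$b), 0)
})

test_that("pairwise terms match a brute-force double loop", {
  set.seed(11)
  nm <- c("CB", "N", "O", "CA", "OG", "NZ", "CB", "C", "OD1", "SG")
  rs <- c("ALA", "ALA", "ALA", "ALA", "SER", "LYS", "LEU", "ALA", "ASP",
          "CYS")
  a <- atom_set(matrix(stats::rnorm(15, sd = 3), 5), rs[1:5], nm[1:5], ff)
  b <- atom_set(matrix(stats::rnorm(15, sd = 3) + 4, 5), rs[6:10],
                nm[6:10], ff)
  orc <- oracle_pairs(a, b, ff)
  expect_equal(vdw_energy(a, b), orc$vw, tolerance = 1e-9)
  expect_equal(electrostatic_energy(a, b), orc$el, tolerance = 1e-9)
  expect_equal(hydrophobic_energy(a, b), orc$hp, tolerance = 1e-9)
})

test_that("pairwise terms are symmetric in their arguments", {
  set.seed(4)
  a <- atom_set(matrix(stats::rnorm(9, sd = 2), 3), c("ALA", "SER", "ASP"),
                c("CB", "OG", "OD1"), ff)
  b <- atom_set(matrix(stats::rnorm(9, sd = 2) + 3, 3),
                c("LYS", "ALA", "ALA"), c("NZ", "O", "N"), ff)
  expect_equal(vdw_energy(a, b), vdw_energy(b, a))
  expect_equal(electrostatic_energy(a, b), electrostatic_energy(b, a))
  expect_equal(hbond_energy(a, b), hbond_energy(b, a))
  expect_equal(hydrophobic_energy(a, b), hydrophobic_energy(b, a))
})

test_that("hydrogen bond term respects the 3.65 A cutoff and geometry", {
  don <- function(d) {
    # backbone N donor with its CA antecedent at the ideal 115 deg
    ca <- c(cos(115 * pi / 180), sin(115 * pi / 180), 0) * 1.458
    atom_set(rbind(c(0, 0, 0), ca), c("ALA", "ALA"), c("N", "CA"), ff)
  }
  acc <- function(d) atom_set(matrix(c(d, 0, 0), 1), "ALA", "O", ff)
  expect_equal(hbond_energy(don(3.7), acc(3.7)), 0)
  expect_equal(hbond_energy(don(2.9), acc(2.9)), -ff$hb_depth,
               tolerance = 1e-6)
  # continuity across the smoothing window edge
  gap <- abs(hbond_energy(don(3.649), acc(3.649)) -
               hbond_energy(don(3.651), acc(3.651)))
  expect_lt(gap, 1e-3)
})

test_that("electrostatics follow the distance-dependent dielectric", {
  # weakly charged pair so neither distance hits the per-pair cap
  mk <- function(r) list(
    a = atom_set(matrix(c(0, 0, 0), 1), "SER", "OG", ff),
    b = atom_set(matrix(c(r, 0, 0), 1), "SER", "OG", ff))
  p1 <- mk(3); p2 <- mk(6)
  # epsilon = 4r makes the pair energy scale as 1/r^2
  expect_equal(electrostatic_energy(p2$a, p2$b),
               electrostatic_energy(p1$a, p1$b) / 4, tolerance = 1e-9)
  neutral <- atom_set(matrix(c(0, 0, 0), 1), "ALA", "CB", ff)
  other <- atom_set(matrix(c(3, 0, 0), 1), "ASP", "OD1", ff)
  expect_equal(electrostatic_energy(neutral, other), 0)
})

test_that("hydrophobic term is apolar-only with a 4.50 A cutoff", {
  ps <- pair_sets(5.0)
  expect_equal(hydrophobic_energy(ps$a, ps$b), 0)
  polar <- atom_set(matrix(c(0, 0, 0), 1), "ALA", "O", ff)
  apolar <- atom_set(matrix(c(3.0, 0, 0), 1), "ALA", "CB", ff)
  expect_equal(hydrophobic_energy(polar, apolar), 0)
  touching <- pair_sets(3.0)
  expect_equal(hydrophobic_energy(touching$a, touching$b), -ff$hp_strength)
})

test_that("numeric SASA matches closed-form sphere areas", {
  lone <- atom_set(matrix(c(0, 0, 0), 1), "ALA", "CB", ff)
  area <- sasa(lone, ff)
  exact <- 4 * pi * (ff$r0[lone$cls] + ff$sasa_probe)^2
  expect_lt(abs(area - exact) / exact, 0.02)
  # two overlapping spheres: analytic cap areas
  d <- 2.5
  two <- atom_set(rbind(c(0, 0, 0), c(d, 0, 0)), c("ALA", "ALA"),
                  c("CB", "CB"), ff)
  R <- ff$r0[two$cls[1]] + ff$sasa_probe
  h <- R - (d^2) / (2 * d)   # cap height for equal radii
  exact2 <- 4 * pi * R^2 - 2 * pi * R * h
  areas <- sasa(two, ff)
  expect_lt(abs(areas[1] - exact2) / exact2, 0.02)
  expect_lt(abs(areas[2] - exact2) / exact2, 0.02)
})

test_that("solvation and entropy terms behave at their limits", {
  # fully exposed peptide far from any receptor: zero entropy penalty
  p <- peptide_conformation("KLAFAVWTL")
  far <- atom_set(matrix(c(500, 500, 500), 1), "ALA", "CB", ff)
  expect_equal(entropy_term(p, far, ff, n_points = 240), 0)
  # glycine peptide has no side-chain entropy at all
  g <- peptide_conformation("GGGGG")
  near <- atom_set(p$coords + 3, p$atoms$code, p$atoms$name, ff)
  expect_equal(entropy_term(g, near, ff, n_points = 240), 0)
  # partially buried lysine: strictly between 0 and the table maximum
  k <- peptide_conformation(c("LYS"))
  wall <- atom_set(as.matrix(expand.grid(x = seq(-3, 3, 3),
                                         y = seq(-3, 3, 3), z = 4.5)),
                   "ALA", "CB", ff)
  e <- entropy_term(k, wall, ff, n_points = 240)
  expect_gt(e, 0)
  expect_lt(e, ff$entropy_max["LYS"])
})

test_that("the docking score applies the printed weights", {
  b0 <- energy_breakdown()
  expect_equal(docking_score(b0), 0)
  bh <- energy_breakdown(E_hb = 1)
  expect_equal(docking_score(bh), 2.53)
  b1 <- energy_breakdown(E_vw = 1, E_en = 1, E_el = 1, E_hb = 1, E_hp = 1,
                         E_solv = 1)
  expect_equal(docking_score(b1), 11.24)
})

test_that("the refinement score is the unweighted six-term sum", {
  expect_equal(refinement_score(energy_breakdown()), 0)
  expect_equal(refinement_score(energy_breakdown(E_tors = 2.5)), 2.5)
  set.seed(2)
  v <- stats::rnorm(6)
  b <- energy_breakdown(E_vw = v[1], E_hb = v[2], E_tors = v[3],
                        E_elec = v[4], E_solv = v[5], E_en = v[6])
  expect_equal(refinement_score(b), sum(v))
  # with unit weights the docking score reduces to the sum of its terms
  bu <- energy_breakdown(E_vw = 1, E_en = 2, E_el = 3, E_hb = 4, E_hp = 5,
                         E_solv = 6)
  expect_equal(docking_score(bu, scoring_weights(1, 1, 1, 1)), 21)
})

test_that("terms are invariant under rigid motion and continuous at cutoffs", {
  set.seed(9)
  a <- atom_set(matrix(stats::rnorm(12, sd = 2), 4),
                c("ALA", "SER", "LYS", "ALA"), c("CB", "OG", "NZ", "O"), ff)
  b <- atom_set(matrix(stats::rnorm(12, sd = 2) + 3, 4),
                c("ASP", "ALA", "ALA", "ALA"), c("OD1", "CB", "N", "CA"),
                ff)
  R <- grooveDock:::.rot_axis(c(1, 2, 3), 53)
  t0 <- c(5, -2, 7)
  move <- function(s) {
    s$xyz <- t(R %*% t(s$xyz)) + rep(t0, each = nrow(s$xyz))
    s
  }
  expect_equal(vdw_energy(a, b), vdw_energy(move(a), move(b)),
               tolerance = 1e-6)
  expect_equal(hbond_energy(a, b), hbond_energy(move(a), move(b)),
               tolerance = 1e-6)
  expect_equal(electrostatic_energy(a, b),
               electrostatic_energy(move(a), move(b)), tolerance = 1e-6)
  # finite-difference continuity at the nonbonded and contact cutoffs
  for (r0 in c(ff$nb_cutoff, ff$vdw_contact_cutoff)) {
    lo <- pair_sets(r0 - 1e-4); hi <- pair_sets(r0 + 1e-4)
    expect_lt(abs(vdw_energy(lo$a, lo$b) - vdw_energy(hi$a, hi$b)), 1e-3)
    expect_lt(abs(hydrophobic_energy(lo$a, lo$b) -
                    hydrophobic_energy(hi$a, hi$b)), 1e-3)
  }
})
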