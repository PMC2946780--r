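# Biased Monte Carlo machinery: Metropolis criterion, probe placement,
# move proposals, local minimization, trajectories.

test_that("Metropolis criterion follows min(1, exp(-dG/RT))", {
  params <- mc_params(seed = 1)
  expect_true(metropolis_accept(0, params))
  expect_true(metropolis_accept(-5, params))
  expect_error(metropolis_accept(Inf, params))
  # dG = RT ln 2 accepts with probability 1/2
  RT <- params$gas_constant * params$temperature_K
  set.seed(42)
  n <- 10000
  acc <- sum(vapply(seq_len(n), function(i)
    metropolis_accept(RT * log(2), params), TRUE))
  sigma <- sqrt(n * 0.5 * 0.5)
  expect_lt(abs(acc - n / 2), 3 * sigma)
})

test_that("the probe lands on the lowest steric node, ties to the first", {
  zero <- array(0, dim = c(5, 5, 5))
  maps0 <- structure(list(
    origin = c(0, 0, 0), spacing = 1, npts = c(5L, 5L, 5L),
    channels = list(vdw_attractive = zero, vdw_repulsive = zero),
    box = NULL), class = "grid_maps")
  pr <- place_probe(maps0)
  # all-zero field: first node of the central third (tie-break by index)
  expect_equal(pr$node, c(2L, 2L, 2L))
  # exhaustive scan oracle on the fixture maps
  env <- fixture_maps()
  maps <- env$maps
  steric <- maps$channels$vdw_attractive + maps$channels$vdw_repulsive
  np <- maps$npts
  lo <- floor((np - 1) / 3) + 1; hi <- ceiling(2 * (np - 1) / 3) + 1
  best <- c(NA, NA, NA); bv <- Inf
  for (i in lo[1]:hi[1]) for (j in lo[2]:hi[2]) for (k in lo[3]:hi[3]) {
    if (steric[i, j, k] < bv) { bv <- steric[i, j, k]; best <- c(i, j, k) }
  }
  pr2 <- place_probe(maps)
  expect_equal(pr2$node, as.integer(best))
})

test_that("move proposals follow the configured mix with fallbacks", {
  p <- peptide_conformation("GGGGG")
  params <- mc_params(seed = 1, move_mix = c(side = 1, backbone = 0,
                                             rigid = 0))
  set.seed(1)
  prop <- propose_move(p, params)
  expect_equal(prop$type, "backbone")  # no rotatable chi in polyglycine
  # empirical frequencies over many proposals
  q <- peptide_conformation("KLA")
  params <- mc_params(seed = 1)
  set.seed(99)
  types <- vapply(seq_len(4000), function(i)
    propose_move(q, params)$type, "")
  freq <- table(factor(types, levels = c("side", "backbone", "rigid")))
  expect_lt(abs(freq[["side"]] / 4000 - 0.5), 3 * sqrt(0.25 / 4000))
  expect_lt(abs(freq[["backbone"]] / 4000 - 0.3), 3 * sqrt(0.21 / 4000))
  expect_lt(abs(freq[["rigid"]] / 4000 - 0.2), 3 * sqrt(0.16 / 4000))
  # zero-magnitude perturbation leaves the conformation unchanged
  z <- mc_params(seed = 1, max_torsion = 0, max_translation = 0,
                 max_rotation = 0)
  set.seed(3)
  pz <- propose_move(q, z)
  expect_equal(pz$conf$coords, q$coords, tolerance = 1e-9)
  # unperturbed torsions stay bit-identical
  set.seed(4)
  pm <- propose_move(q, mc_params(seed = 1))
  untouched <- setdiff(seq_along(q$torsions), pm$tor_idx)
  if (!pm$rigid)
    expect_identical(pm$conf$torsions[untouched], q$torsions[untouched])
})

test_that("local minimization descends and solves a quadratic exactly", {
  p <- peptide_conformation("KLA")
  target <- 37
  energy <- function(conf) (conf$torsions[["chi1_1"]] - target)^2
  idx <- which(names(p$torsions) == "chi1_1")
  p$torsions[idx] <- 30
  out <- local_minimize(p, energy, mc_params(),
                        vars = list(tor = idx, rigid = FALSE))
  expect_lt(abs(out$conf$torsions[[idx]] - target), 1e-3)
  expect_lte(out$value, energy(p))
  # already at the minimum: returned unchanged within tolerance
  p$torsions[idx] <- target
  out2 <- local_minimize(p, energy, mc_params(),
                         vars = list(tor = idx, rigid = FALSE))
  expect_lt(abs(out2$conf$torsions[[idx]] - target), 1e-3)
})

test_that("docking trajectories are deterministic and monotone in best score", {
  env <- fixture_maps()
  sp <- env$split
  lig <- set_extended_conformation(sp$ligand, seed = 5, box = env$box)
  params <- mc_params(seed = 5, n_steps = 120, patience = 120,
                      init_orientations = 1)
  t1 <- run_docking(env$maps, lig, params)
  t2 <- run_docking(env$maps, lig, params)
  expect_identical(t1$best$torsions, t2$best$torsions)
  expect_identical(t1$best$coords, t2$best$coords)
  expect_identical(t1$accepted, t2$accepted)
  expect_identical(t1$best_trace, t2$best_trace)
  # best-so-far objective never increases
  expect_true(all(diff(t1$best_trace) <= 1e-9))
})

test_that("a zero-step run returns the initial pose only", {
  env <- fixture_maps()
  lig <- env$fx$native
  params <- mc_params(seed = 1, n_steps = 0, patience = 1,
                      init_orientations = 1, anchor_to_probe = FALSE)
  traj <- run_docking(env$maps, lig, params)
  expect_equal(traj$steps_run, 0L)
  expect_equal(nrow(traj$accepted), 0L)
  expect_equal(traj$best$coords, lig$coords)
})

test_that("docking finds poses at least as good as a displaced native", {
  env <- fixture_maps()
  sp <- env$split
  lig <- set_extended_conformation(sp$ligand, seed = 2, box = env$box)
  params <- mc_params(seed = 2, n_steps = 500, patience = 500)
  traj <- run_docking(env$maps, lig, params)
  shifted <- env$fx$native
  shifted$translation <- shifted$translation + c(0, 0, 5)
  shifted <- rebuild_coords(shifted)
  ctx <- dock_context(env$maps, shifted)
  e_shifted <- pose_energy(ctx, shifted)$score
  expect_lte(traj$best_score, e_shifted)
})

test_that("stiff positional restraints freeze the ligand", {
  env <- fixture_maps()
  lig <- env$fx$native
  params <- mc_params(seed = 3, n_steps = 150, patience = 150,
                      restraint_k = 1e6, init_orientations = 1,
                      anchor_to_probe = FALSE)
  traj <- run_docking(env$maps, lig, params)
  start <- traj$start_pose
  disp <- sqrt(max(rowSums((traj$final$coords[traj$final$ca_idx, ] -
                              start$coords[start$ca_idx, ])^2)))
  expect_lt(disp, 0.5)
})
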