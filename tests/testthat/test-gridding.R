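# Docking box, binding-site spheres and grid potential maps.

test_that("class-default box dimensions match the standardized values", {
  expect_identical(class_box_dims("I"), c(35.36, 35.52, 35.79))
  expect_identical(class_box_dims("II"), c(58.32, 56.36, 48.87))
  expect_error(class_box_dims("III"), "override_dims")
})

test_that("the box centers on the groove and encloses its atoms", {
  env <- fixture_maps()
  box <- env$box
  gca <- env$split$receptor[env$split$receptor$groove &
                              env$split$receptor$elety == "CA", ]
  expect_equal(box$center, unname(colMeans(as.matrix(gca[, c("x", "y",
                                                             "z")]))),
               tolerance = 1e-9)
  # all native peptide atoms and groove atoms inside the (possibly
  # expanded) box
  lo <- box$center - box$dims / 2
  hi <- box$center + box$dims / 2
  pc <- env$fx$native$coords
  expect_true(all(t(pc) >= lo - 1e-9 & t(pc) <= hi + 1e-9))
  gxyz <- as.matrix(env$split$receptor[env$split$receptor$groove,
                                       c("x", "y", "z")])
  expect_true(all(t(gxyz) >= lo - 1e-9 & t(gxyz) <= hi + 1e-9))
})

test_that("binding-site spheres select atoms in and on the 5 A radius", {
  # toy receptor: CA atoms along x define the axis, test atoms offset in y
  n <- 11
  rec <- data.frame(elety = "CA", resid = "ALA", chain = "A", resno = 1:n,
                    x = seq(-15, 15, length.out = n), y = 0, z = 0,
                    groove = TRUE, stringsAsFactors = FALSE)
  box <- structure(list(center = c(0, 0, 0), dims = c(30, 20, 20),
                        mhc_class = "I"), class = "docking_box")
  site0 <- select_binding_site(rec, box)
  centers <- site0$centers
  probe_on <- rec[1, ]; probe_on$elety <- "CB"
  probe_on$x <- centers[1, 1]; probe_on$y <- 5.00; probe_on$z <- 0
  probe_off <- probe_on
  probe_off$y <- 5.01
  # keep probes clear of every other center
  d_on <- min(sqrt(colSums((t(centers) -
                              as.numeric(probe_on[c("x", "y", "z")]))^2)))
  expect_equal(d_on, 5.00, tolerance = 1e-9)
  rec2 <- rbind(rec, probe_on, probe_off)
  site <- select_binding_site(rec2, box)
  expect_true((n + 1L) %in% site$atom_idx)   # exactly on the sphere
  expect_false((n + 2L) %in% site$atom_idx)  # just outside
})

test_that("grid maps store the direct receptor field at the nodes", {
  env <- fixture_maps()
  maps <- env$maps
  expect_equal(maps$npts, floor(env$box$dims / maps$spacing) + 1L)
  # a corner node far from every receptor atom carries ~zero field
  corner <- vapply(maps$channels[1:6], function(ch) ch[1, 1, 1], 1)
  expect_true(all(abs(corner) < 0.05))
  # random nodes equal the direct field evaluation to 1e-9
  set.seed(5)
  ijk <- cbind(sample(maps$npts[1], 20, TRUE), sample(maps$npts[2], 20,
                                                      TRUE),
               sample(maps$npts[3], 20, TRUE))
  pts <- sweep((ijk - 1) * maps$spacing, 2, maps$origin, "+")
  r <- maps$receptor_set
  fld <- grooveDock:::receptor_field_cpp(
    pts, r$xyz, r$cls, r$charge, as.integer(r$donor), as.integer(r$donp),
    as.integer(r$acceptor), as.integer(r$apolar),
    grooveDock:::.ff_cpp(default_forcefield()))
  for (k in seq_len(20)) {
    stored <- vapply(maps$channels, function(ch)
      ch[ijk[k, 1], ijk[k, 2], ijk[k, 3]], 1)
    expect_equal(unname(stored), unname(fld[k, ]), tolerance = 1e-9)
  }
})

test_that("electrostatic channel matches an independent Coulomb sum", {
  # plain-R oracle for the screened Coulomb field at a node
  env <- fixture_maps()
  maps <- env$maps
  ff <- default_forcefield()
  r <- maps$receptor_set
  set.seed(8)
  for (rep in 1:5) {
    ijk <- c(sample(maps$npts[1], 1), sample(maps$npts[2], 1),
             sample(maps$npts[3], 1))
    pt <- maps$origin + (ijk - 1) * maps$spacing
    d <- sqrt(colSums((t(r$xyz) - pt)^2))
    sw <- function(x, on, off) {
      t <- pmin(1, pmax(0, (x - on) / (off - on)))
      1 - t^2 * (3 - 2 * t)
    }
    v <- ff$coulomb_k * r$charge / (4 * pmax(d, 0.5)^2)
    v <- pmax(pmin(v, ff$elec_cap), -ff$elec_cap)
    oracle <- sum(v[d <= ff$nb_cutoff] *
                    sw(d[d <= ff$nb_cutoff], ff$nb_cutoff - 1,
                       ff$nb_cutoff))
    expect_equal(maps$channels$electrostatic[ijk[1], ijk[2], ijk[3]],
                 oracle, tolerance = 1e-9)
  }
})

test_that("grid interpolation is exact on nodes and penalizes outside atoms", {
  env <- fixture_maps()
  maps <- env$maps
  ijk <- c(10L, 12L, 9L)
  node <- maps$origin + (ijk - 1) * maps$spacing
  one <- atom_set(matrix(node, 1), "ALA", "CB")
  b <- grid_energy(maps, one)
  expect_equal(b$E_vw,
               maps$channels$vdw_attractive[ijk[1], ijk[2], ijk[3]] +
                 maps$channels$vdw_repulsive[ijk[1], ijk[2], ijk[3]],
               tolerance = 1e-9)
  expect_equal(b$E_hp,
               maps$channels$hydrophobic[ijk[1], ijk[2], ijk[3]],
               tolerance = 1e-9)
  # whole ligand outside the box: penalty per atom, nothing else
  p <- env$fx$native
  p$translation <- p$translation + c(500, 0, 0)
  p <- rebuild_coords(p)
  bo <- grid_energy(maps, p)
  expect_equal(bo$E_vw, nrow(p$coords) * maps$out_of_box_penalty)
  expect_equal(bo$E_el, 0)
  expect_equal(bo$E_hb, 0)
})

test_that("maps depend only on the receptor", {
  env <- fixture_maps()
  m2 <- build_grid_maps(env$split$receptor, env$site, env$box)
  expect_identical(env$maps$channels, m2$channels)
  expect_identical(env$maps$origin, m2$origin)
})

test_that("grid and direct energies agree, improving with finer spacing", {
  env <- fixture_maps()
  poses <- random_box_poses(30, seed = 21)
  rl_sum <- function(b) b$E_vw + b$E_el + b$E_hb + b$E_hp
  err1 <- vapply(poses, function(p)
    abs(rl_sum(grid_energy(env$maps, p)) -
          rl_sum(direct_receptor_energy(env$maps, p))), 1)
  expect_lt(stats::median(err1), 0.5)
  maps_fine <- build_grid_maps(env$split$receptor, env$site, env$box,
                               spacing = 0.5)
  err2 <- vapply(poses, function(p)
    abs(rl_sum(grid_energy(maps_fine, p)) -
          rl_sum(direct_receptor_energy(maps_fine, p))), 1)
  expect_lt(stats::median(err2), stats::median(err1))
})
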