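# RMSD metric, register detection, correctness calls, non-redundancy
# filtering and interface refinement.

test_that("core C-alpha RMSD is an exact metric", {
  fx <- default_fixture()
  p <- fx$native
  expect_equal(ca_rmsd(p, p), 0)
  # uniform translation by 1.3 A gives exactly 1.30
  q <- p
  q$translation <- q$translation + 1.3 * c(1, 0, 0)
  q <- rebuild_coords(q)
  expect_equal(ca_rmsd(q, p), 1.3, tolerance = 1e-9)
  # brute-force agreement on random coordinate sets
  set.seed(7)
  A <- matrix(stats::rnorm(27), 9)
  B <- matrix(stats::rnorm(27), 9)
  expect_equal(ca_rmsd(A, B), sqrt(mean(rowSums((A - B)^2))),
               tolerance = 1e-12)
  # symmetry and triangle inequality on random triples
  for (i in 1:10) {
    A <- matrix(stats::rnorm(27), 9)
    B <- matrix(stats::rnorm(27), 9)
    C <- matrix(stats::rnorm(27), 9)
    expect_equal(ca_rmsd(A, B), ca_rmsd(B, A))
    expect_lte(ca_rmsd(A, C), ca_rmsd(A, B) + ca_rmsd(B, C) + 1e-12)
  }
  expect_error(ca_rmsd(A[1:8, ], B), "different lengths")
})

test_that("RMSD uses the core window for long peptides", {
  set.seed(3)
  A <- matrix(stats::rnorm(39), 13)
  B <- A
  B[1:2, ] <- B[1:2, ] + 50    # flanks outside the register-3 core
  B[12:13, ] <- B[12:13, ] + 50
  expect_equal(ca_rmsd(A, B, register = 3L), 0)
  expect_gt(ca_rmsd(A, B, register = 1L), 1)
})

test_that("superposed RMSD removes a rigid frame difference", {
  set.seed(8)
  A <- matrix(stats::rnorm(27, sd = 4), 9)
  R <- grooveDock:::.rot_axis(c(1, 1, 0), 30)
  moved <- t(R %*% t(A)) + rep(c(3, -2, 1), each = 9)
  recA <- matrix(stats::rnorm(60, sd = 8), 20)
  rec_moved <- t(R %*% t(recA)) + rep(c(3, -2, 1), each = 20)
  expect_gt(ca_rmsd(moved, A), 1)
  expect_lt(ca_rmsd(moved, A, superpose = TRUE, fit_mobile = rec_moved,
                    fit_target = recA), 1e-6)
})

test_that("correctness classification uses an inclusive 2.50 A bound", {
  expect_true(classify_correct(2.50))
  expect_false(classify_correct(2.51))
  expect_true(classify_correct(0.56))
  expect_error(classify_correct(-0.1), "non-negative")
})

test_that("register detection recovers the constructed window", {
  fx <- default_fixture()
  env <- fixture_maps()
  expect_equal(detect_register(fx$native, env$site)$start, 1L)
  # 13-mer built with its core at register 3
  spec13 <- fixture_spec(seed = 11, peptide_length = 13, register = 3)
  fx13 <- suppressWarnings(generate_mini_groove(spec13))
  sp13 <- split_complex(fx13$complex)
  box13 <- suppressWarnings(make_docking_box(fx13$complex))
  site13 <- select_binding_site(sp13$receptor, box13)
  expect_equal(fx13$truth$register, 3L)
  expect_equal(detect_register(fx13$native, site13)$start, 3L)
  # all-tie case (no contacts at all) resolves to the smallest start
  far_site <- site13
  far_site$coords <- site13$coords + 500
  expect_equal(detect_register(fx13$native, far_site)$start, 1L)
})

test_that("non-redundancy filtering keeps the best resolution per group", {
  entries <- data.frame(
    pdb_id = c("1aaa", "1bbb", "1ccc", "1ddd", "1eee"),
    peptide = c("KLFGAVWTL", "KLFGAVWTL", "SIINFEKL", "KLFGAVWTL",
                "KLFGAVWTL"),
    allele = c("A*0201", "A*0201", "Kb", "A*0201", "A*0201"),
    tr_type = c(NA, NA, NA, "TRAV12", "TRBV9"),
    resolution = c(2.4, 1.8, 2.1, 2.9, 3.1),
    stringsAsFactors = FALSE)
  kept <- select_nonredundant(entries)
  # same peptide+allele without TR: only the 1.8 A structure survives
  expect_true("1bbb" %in% kept$pdb_id)
  expect_false("1aaa" %in% kept$pdb_id)
  expect_true("1ccc" %in% kept$pdb_id)
  # same peptide+allele but different TR types: both kept
  expect_true(all(c("1ddd", "1eee") %in% kept$pdb_id))
  # idempotent
  expect_identical(select_nonredundant(kept), kept)
  # tie on resolution: lexicographically first pdb id
  tie <- data.frame(pdb_id = c("2zzz", "2aaa"), peptide = "AAA",
                    allele = "X", resolution = c(2, 2),
                    stringsAsFactors = FALSE)
  expect_equal(select_nonredundant(tie)$pdb_id, "2aaa")
})

test_that("refinement lowers the score and only moves the 4 A interface", {
  fx <- default_fixture()
  sp <- split_complex(fx$complex)
  pose <- fx$native
  out <- refine_interface(sp$receptor, pose, sweeps = 1, sasa_points = 60)
  expect_lte(out$score_after, out$score_before + 1e-9)
  # receptor residues entirely beyond 4 A of the ligand never move
  mind <- grooveDock:::.min_cross_dist(
    as.matrix(sp$receptor[, c("x", "y", "z")]), pose$coords)
  key <- paste(sp$receptor$chain, sp$receptor$resno)
  far_res <- setdiff(unique(key), unique(key[mind <= 4.0]))
  far_rows <- key %in% far_res
  expect_identical(as.matrix(out$receptor[far_rows, c("x", "y", "z")]),
                   as.matrix(sp$receptor[far_rows, c("x", "y", "z")]))
})

test_that("refinement resolves an engineered clash", {
  fx <- default_fixture()
  sp <- split_complex(fx$complex)
  rxyz <- as.matrix(sp$receptor[, c("x", "y", "z")])
  clash_count <- function(xyz, ref = rxyz)
    grooveDock:::contact_count_cpp(xyz, ref, 0.8 * 3.6)
  # push the native pose into the groove floor to create clashes
  clashed <- fx$native
  clashed$translation <- clashed$translation + c(0, 0, -1.3)
  clashed <- rebuild_coords(clashed)
  n_before <- clash_count(clashed$coords)
  expect_gt(n_before, 0)
  out <- refine_interface(sp$receptor, clashed, sweeps = 1,
                          sasa_points = 60, restraint_k = 0.2)
  n_after <- clash_count(out$pose$coords,
                         as.matrix(out$receptor[, c("x", "y", "z")]))
  expect_lt(n_after, n_before)
})

test_that("refinement leaves a distant receptor untouched", {
  fx <- default_fixture()
  sp <- split_complex(fx$complex)
  far_rec <- sp$receptor
  far_rec[, c("x", "y", "z")] <- far_rec[, c("x", "y", "z")] + 100
  out <- refine_interface(far_rec, fx$native, sweeps = 1, sasa_points = 60)
  expect_identical(as.matrix(out$receptor[, c("x", "y", "z")]),
                   as.matrix(far_rec[, c("x", "y", "z")]))
})
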