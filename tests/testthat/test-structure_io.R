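test_that("PDB round trip preserves atoms, names, residues and coordinates", {
  fx <- default_fixture()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_file(fx$complex, f)
  cx2 <- read_pmhc(f)
  expect_equal(nrow(cx2$atoms), nrow(fx$complex$atoms))
  expect_equal(cx2$atoms$elety, fx$complex$atoms$elety)
  expect_equal(cx2$atoms$resid, fx$complex$atoms$resid)
  expect_equal(as.matrix(cx2$atoms[, c("x", "y", "z")]),
               as.matrix(fx$complex$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(length(unique(cx2$atoms$resno[cx2$peptide_idx])), 9L)
  expect_equal(cx2$peptide_chain, "P")
})

test_that("malformed PDB records raise an error naming the line", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00",
    "ATOM      2  CA  ALA A   1      xxxxxx   5.000  -6.000  1.00  0.00"),
    f)
  expect_error(read_pmhc(f), "line 2")
})

test_that("alternate locations resolve to the highest occupancy", {
  fx <- default_fixture()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_file(fx$complex, f)
  lines <- readLines(f)
  i <- grep("^ATOM", lines)[1]
  base <- lines[i]
  total <- length(grep("^ATOM|^HETATM", lines))
  altA <- base
  substr(altA, 17, 17) <- "A"
  substr(altA, 55, 60) <- "  0.60"
  altB <- base
  substr(altB, 17, 17) <- "B"
  substr(altB, 55, 60) <- "  0.40"
  substr(altB, 31, 38) <- sprintf("%8.3f",
                                  as.numeric(substr(base, 31, 38)) + 0.5)
  lines <- c(lines[seq_len(i - 1)], altA, altB, lines[-seq_len(i)])
  writeLines(lines, f)
  cx <- read_pmhc(f)
  expect_equal(nrow(cx$atoms), total)  # one altloc copy dropped
  kept <- cx$atoms[1, ]
  expect_equal(kept$o, 0.60)
  expect_equal(kept$x, as.numeric(substr(base, 31, 38)))
})

test_that("hetero groups are parsed and excluded unless requested", {
  fx <- default_fixture()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_file(fx$complex, f)
  lines <- readLines(f)
  fmt <- c(
    "HETATM9991  C   FMT H 901       0.000   0.000   9.000  1.00  0.00           C",
    "HETATM9992  O1  FMT H 901       1.100   0.000   9.300  1.00  0.00           O",
    "HETATM9993  O2  FMT H 901      -0.700   0.900   9.500  1.00  0.00           O")
  writeLines(c(lines[lines != "END"], fmt, "END"), f)
  cx <- read_pmhc(f)
  expect_length(cx$hetero, 1L)
  sp0 <- split_complex(cx, include_hetero = FALSE)
  sp1 <- split_complex(cx, include_hetero = TRUE)
  expect_equal(nrow(sp1$receptor) - nrow(sp0$receptor), 3L)
  expect_equal(sp0$n_skipped_hetero, 3L)
  # partition: receptor + ligand heavy atoms + skipped hetero = total
  expect_equal(nrow(sp0$receptor) + length(cx$peptide_idx) +
                 sp0$n_skipped_hetero, nrow(cx$atoms))
})

test_that("ligand extraction copies the crystal coordinates", {
  fx <- default_fixture()
  sp <- split_complex(fx$complex)
  pep_atoms <- fx$complex$atoms[fx$complex$peptide_idx, ]
  have <- attr(sp$ligand, "crystal_match")
  expect_true(all(have))
  idx <- match(paste(sp$ligand$atoms$residue_index, sp$ligand$atoms$name),
               paste(pep_atoms$resno, pep_atoms$elety))
  expect_equal(unname(sp$ligand$coords),
               unname(as.matrix(pep_atoms[idx, c("x", "y", "z")])))
})

test_that("extended randomization is deterministic with trans backbone", {
  p <- peptide_conformation("KLAFAVWTL")
  e1 <- set_extended_conformation(p, seed = 7)
  e2 <- set_extended_conformation(p, seed = 7)
  expect_identical(e1$torsions, e2$torsions)
  expect_true(all(e1$torsions[e1$torsion_kind == "omega"] == 180))
  # extended chain is longer end-to-end than a compact helical one
  compact <- p
  compact$torsions[p$torsion_kind == "phi"] <- -60
  compact$torsions[p$torsion_kind == "psi"] <- -45
  compact <- rebuild_coords(compact)
  d_ext <- sqrt(sum((e1$coords[e1$ca_idx[9], ] - e1$coords[e1$ca_idx[1], ])^2))
  d_cmp <- sqrt(sum((compact$coords[compact$ca_idx[9], ] -
                       compact$coords[compact$ca_idx[1], ])^2))
  expect_gt(d_ext, d_cmp)
})

test_that("core extraction follows the nonamer window rules", {
  p8 <- peptide_conformation("KLAFAVWT")
  core8 <- extract_core(p8, 1L)
  expect_true(core8$whole_peptide)
  expect_equal(core8$residues, 1:8)

  p13 <- peptide_conformation(paste(rep("A", 13), collapse = ""))
  core13 <- extract_core(p13, 3L)
  expect_equal(core13$residues, 3:11)
  expect_error(extract_core(p13, 6L), "exceeds")

  p9 <- peptide_conformation("KLAFAVWTL")
  core9 <- extract_core(p9, 5L)  # forced to the single window
  expect_equal(core9$residues, 1:9)
})

test_that("torsion to Cartesian rebuild round-trips", {
  for (seqs in c("KLAFAVWTL", "WIRDHNEQC", "PMSTYVKFG")) {
    p <- peptide_conformation(seqs)
    p <- set_extended_conformation(p, seed = 3)
    m <- measure_torsions(p)
    dev <- abs(grooveDock:::.wrap_angle(m - p$torsions))
    # inert placeholders (first phi/omega) are not measured
    meas <- !(p$torsion_res == 1 & p$torsion_kind %in% c("phi", "omega"))
    expect_lt(max(dev[meas]), 1e-6)
    # rebuilding from measured torsions reproduces coordinates
    q <- p
    q$torsions[meas] <- m[meas]
    q <- rebuild_coords(q)
    expect_equal(q$coords, p$coords, tolerance = 1e-6)
  }
})

test_that("analogue residues map to standard parents", {
  am <- map_analogue(c("MSE", "ALA", "XYZ"))
  expect_equal(am$parent_code, c("MET", "ALA", "ALA"))
  expect_equal(am$is_analogue, c(TRUE, FALSE, TRUE))
  p <- peptide_conformation(c("MSE", "ALA", "GLY", "LYS", "SER", "THR"))
  expect_equal(p$parent_codes[1], "MET")
  expect_true(p$is_analogue[1])
  expect_equal(p$codes[1], "MSE")
})
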