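# Shared fixtures, generated once per test run.

.fx_cache <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (is.null(.fx_cache$fx)) {
    .fx_cache$fx <- suppressWarnings(generate_mini_groove(fixture_spec()))
  }
  .fx_cache$fx
}

fixture_maps <- function() {
  if (is.null(.fx_cache$maps)) {
    fx <- default_fixture()
    sp <- split_complex(fx$complex)
    box <- suppressWarnings(make_docking_box(fx$complex))
    site <- select_binding_site(sp$receptor, box)
    .fx_cache$maps <- build_grid_maps(sp$receptor, site, box)
    .fx_cache$split <- sp
    .fx_cache$box <- box
    .fx_cache$site <- site
  }
  list(maps = .fx_cache$maps, split = .fx_cache$split, box = .fx_cache$box,
       site = .fx_cache$site, fx = default_fixture())
}

# random clash-free rigid/torsion poses of the fixture peptide inside the
# docking box (used by the grid/direct oracle checks)
random_box_poses <- function(n, seed = 1, min_clearance = 3.4) {
  env <- fixture_maps()
  fx <- env$fx
  box <- env$box
  rxyz <- env$maps$receptor_set$xyz
  set.seed(seed)
  poses <- list()
  guard <- 0
  lo <- env$maps$origin
  hi <- env$maps$origin + (env$maps$npts - 1) * env$maps$spacing
  while (length(poses) < n && guard < n * 200) {
    guard <- guard + 1
    p <- fx$native
    chi <- grepl("^chi", p$torsion_kind) & p$parent_codes[p$torsion_res] !=
      "PRO"
    p$torsions[chi] <- stats::runif(sum(chi), -180, 180)
    qn <- stats::rnorm(4); qn <- qn / sqrt(sum(qn^2))
    p$rotation <- grooveDock:::.quat_to_mat(qn)
    p <- rebuild_coords(p)
    cen <- colMeans(p$coords)
    base <- p$coords
    # many cheap translations per conformation draw: a rigid shift moves
    # the coordinates by a constant vector, no rebuild needed
    for (tr in seq_len(40)) {
      target <- box$center + stats::runif(3, -0.35, 0.35) * box$dims
      shift <- target - cen
      xyz <- sweep(base, 2, shift, "+")
      inside <- all(t(xyz) >= lo) && all(t(xyz) <= hi)
      if (!inside) next
      if (grooveDock:::contact_count_cpp(rxyz, xyz, min_clearance) > 0)
        next
      q <- p
      q$translation <- q$translation + shift
      poses[[length(poses) + 1]] <- rebuild_coords(q)
      if (length(poses) >= n) break
    }
  }
  poses
}

# strip volatile fields from reports for determinism comparisons
strip_times <- function(report) {
  report$cases <- lapply(report$cases, function(cs) {
    cs$time_s <- NULL
    cs
  })
  report
}
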