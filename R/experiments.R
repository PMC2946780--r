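# End-to-end docking pipelines: re-docking, single-template and
# variant-template experiments, antigen scanning and JSON reports.

#' Re-dock a peptide into its cognate groove
#'
#' The full single-complex pipeline: split the complex, randomize the
#' peptide to an extended conformation, build the docking box, select the
#' binding site, precompute grid maps, run biased Monte Carlo docking
#' (optionally over several seeded replicas, keeping the overall best
#' pose), refine the interface within 4 A, then report the detected
#' register, the core C-alpha RMSD against the crystal pose in the shared
#' receptor frame, and the correctness call.
#'
#' @param cx A `pmhc` complex (or a PDB path).
#' @param mc `mc_params` controlling the sampling (its `seed` drives all
#'   randomness, its `replicas` the number of trajectories).
#' @param ff Force field.
#' @param weights Scoring weights.
#' @param include_hetero Keep hetero groups on the receptor side.
#' @param refine Run interface refinement on the best pose.
#' @param refine_args Extra arguments for [refine_interface()].
#' @return list: the docked/refined pose, trajectory, register, `rmsd`,
#'   `correct`, energies and bookkeeping.
#' @export
redock <- function(cx, mc = mc_params(n_steps = 5000, patience = 1800,
                                       replicas = 4),
                   ff = default_forcefield(),
                   weights = scoring_weights(), include_hetero = FALSE,
                   refine = TRUE, refine_args = list()) {
  if (is.character(cx)) cx <- read_pmhc(cx)
  t0 <- proc.time()[3]
  sp <- split_complex(cx, include_hetero = include_hetero)
  native_ca <- attr(sp$ligand, "reference_ca")
  box <- make_docking_box(cx)
  site <- select_binding_site(sp$receptor, box)
  maps <- build_grid_maps(sp$receptor, site, box, ff)
  best_traj <- NULL
  for (k in seq_len(mc$replicas)) {
    mck <- mc
    mck$seed <- mc$seed + 7919L * (k - 1L)
    # re-docking positions the ligand from the original structure: the
    # internal conformation is randomized and extended while the
    # rigid-body placement is inherited, so no reorientation screen runs
    mck$init_orientations <- 1L
    lig_k <- set_extended_conformation(sp$ligand, seed = mck$seed,
                                       box = NULL)
    traj <- run_docking(maps, lig_k, mck, ff, weights)
    if (is.null(best_traj) ||
          traj$best_objective < best_traj$best_objective)
      best_traj <- traj
  }
  pose <- best_traj$best
  ref <- NULL
  if (refine) {
    ref <- do.call(refine_interface,
                   c(list(receptor = sp$receptor, pose = pose, ff = ff),
                     refine_args))
    pose <- ref$pose
  }
  reg <- detect_register(pose, site)
  rmsd <- ca_rmsd(pose, native_ca, register = reg$start)
  list(pose = pose, trajectory = best_traj, refinement = ref,
       register = reg, rmsd = rmsd, correct = classify_correct(rmsd),
       best_score = best_traj$best_score,
       refined_score = if (refine) ref$score_after else NA_real_,
       sequence = pose$sequence, seed = mc$seed, maps = maps, site = site,
       box = box, native_ca = native_ca,
       time_s = unname(proc.time()[3] - t0))
}

#' Dock a peptide sequence onto a receptor template
#'
#' Template-docking pipeline for peptides given only by sequence
#' (experiments on novel epitopes): the template's own peptide defines
#' the groove and is then discarded; the query peptide starts from a
#' randomized extended conformation.
#'
#' @param template A `pmhc` complex (or PDB path) providing the receptor.
#' @param peptide Peptide sequence (one-letter string).
#' @param reference Optional reference `pmhc` or C-alpha matrix for RMSD.
#' @inheritParams redock
#' @return list like [redock()] (RMSD fields NA without a reference).
#' @export
dock_template <- function(template, peptide, reference = NULL,
                          mc = mc_params(), ff = default_forcefield(),
                          weights = scoring_weights(), refine = TRUE,
                          refine_args = list()) {
  if (is.character(template)) template <- read_pmhc(template)
  t0 <- proc.time()[3]
  sp <- split_complex(template)
  box <- make_docking_box(template)
  site <- select_binding_site(sp$receptor, box)
  maps <- build_grid_maps(sp$receptor, site, box, ff)
  lig <- peptide_conformation(peptide)
  lig <- set_extended_conformation(lig, seed = mc$seed, box = box)
  best_traj <- NULL
  for (k in seq_len(mc$replicas)) {
    mck <- mc
    mck$seed <- mc$seed + 7919L * (k - 1L)
    if (mc$replicas > 1)  # replicas alternate groove directions
      mck$direction <- c("axis+", "axis-")[((k - 1L) %% 2L) + 1L]
    lig_k <- if (k == 1L) lig else
      set_extended_conformation(peptide_conformation(peptide),
                                seed = mck$seed, box = box)
    traj <- run_docking(maps, lig_k, mck, ff, weights)
    if (is.null(best_traj) ||
          traj$best_objective < best_traj$best_objective)
      best_traj <- traj
  }
  pose <- best_traj$best
  ref <- NULL
  if (refine) {
    ref <- do.call(refine_interface,
                   c(list(receptor = sp$receptor, pose = pose, ff = ff),
                     refine_args))
    pose <- ref$pose
  }
  reg <- detect_register(pose, site)
  rmsd <- NA_real_
  if (!is.null(reference)) {
    ref_ca <- if (inherits(reference, "pmhc")) {
      rsp <- split_complex(reference)
      attr(rsp$ligand, "reference_ca")
    } else as.matrix(reference)
    if (nrow(ref_ca) == pose$nres)
      rmsd <- ca_rmsd(pose, ref_ca, register = reg$start)
  }
  list(pose = pose, trajectory = best_traj, refinement = ref,
       register = reg, rmsd = rmsd,
       correct = if (is.na(rmsd)) NA else classify_correct(rmsd),
       best_score = best_traj$best_score,
       refined_score = if (refine) ref$score_after else NA_real_,
       sequence = pose$sequence, seed = mc$seed,
       time_s = unname(proc.time()[3] - t0))
}

#' Run a docking experiment over a batch of cases
#'
#' Orchestrates the three experiment modes: `redock` (peptides extracted,
#' randomized and re-docked into their cognate grooves), `single_template`
#' (multiple peptide sequences docked onto one receptor template) and
#' `variant_template` (one peptide docked onto multiple templates). A
#' failing case is reported as an error entry; the run continues.
#'
#' @param mode One of "redock", "single_template", "variant_template".
#' @param inputs For `redock`: a list of complexes, PDB paths or
#'   `fixture_spec`s. For `single_template`: list(template=, peptides=,
#'   references= optional). For `variant_template`: list(templates=,
#'   peptide=, references= optional).
#' @param mc,ff,weights,refine,refine_args Passed to the per-case
#'   pipeline.
#' @return list of class `groove_report`: `mode`, per-case summaries,
#'   `fraction_correct` (over cases with an RMSD), the parameter echo and
#'   per-case timings.
#' @export
run_experiment <- function(mode = c("redock", "single_template",
                                    "variant_template"),
                           inputs, mc = mc_params(),
                           ff = default_forcefield(),
                           weights = scoring_weights(), refine = TRUE,
                           refine_args = list()) {
  mode <- match.arg(mode)
  run_case <- function(id, fn) {
    tryCatch({
      r <- fn()
      list(id = id, sequence = r$sequence, register = r$register$start,
           rmsd = r$rmsd, correct = r$correct,
           best_score = r$best_score, refined_score = r$refined_score,
           seed = r$seed, time_s = r$time_s, error = NULL)
    }, error = function(e) {
      list(id = id, error = conditionMessage(e))
    })
  }
  cases <- list()
  if (mode == "redock") {
    for (i in seq_along(inputs)) {
      inp <- inputs[[i]]
      mci <- mc
      mci$seed <- mc$seed + 101L * (i - 1L)
      cases[[i]] <- run_case(i, function() {
        cx <- if (inherits(inp, "fixture_spec"))
          generate_mini_groove(inp)$complex else inp
        redock(cx, mc = mci, ff = ff, weights = weights, refine = refine,
               refine_args = refine_args)
      })
    }
  } else if (mode == "single_template") {
    template <- inputs$template
    if (is.character(template)) template <- read_pmhc(template)
    peps <- inputs$peptides
    for (i in seq_along(peps)) {
      mci <- mc
      mci$seed <- mc$seed + 101L * (i - 1L)
      refi <- inputs$references[[i]] %||% NULL
      cases[[i]] <- run_case(i, function()
        dock_template(template, peps[i], reference = refi, mc = mci,
                      ff = ff, weights = weights, refine = refine,
                      refine_args = refine_args))
    }
    # rank by refined (or docking) score
    sc <- vapply(cases, function(cse)
      if (is.null(cse$error)) {
        if (!is.na(cse$refined_score)) cse$refined_score else cse$best_score
      } else Inf, 1)
    cases <- cases[order(sc)]
  } else {
    tmps <- inputs$templates
    for (i in seq_along(tmps)) {
      mci <- mc
      mci$seed <- mc$seed + 101L * (i - 1L)
      refi <- inputs$references[[i]] %||% NULL
      cases[[i]] <- run_case(i, function()
        dock_template(tmps[[i]], inputs$peptide, reference = refi,
                      mc = mci, ff = ff, weights = weights,
                      refine = refine, refine_args = refine_args))
    }
  }
  rmsds <- vapply(cases, function(cse)
    if (is.null(cse$error) && !is.null(cse$rmsd)) cse$rmsd else NA_real_, 1)
  correct <- vapply(cases, function(cse)
    if (is.null(cse$error) && !is.null(cse$correct)) cse$correct else NA, TRUE)
  structure(list(
    mode = mode, cases = cases,
    n_cases = length(cases),
    n_errors = sum(vapply(cases, function(cse) !is.null(cse$error), TRUE)),
    mean_rmsd = if (any(!is.na(rmsds))) mean(rmsds, na.rm = TRUE) else
      NA_real_,
    fraction_correct = if (any(!is.na(correct)))
      mean(correct, na.rm = TRUE) else NA_real_,
    seed = mc$seed,
    config = list(mc = unclass(mc), weights = unclass(weights),
                  refine = refine, ff_checksum = ff$table_checksum)),
    class = "groove_report")
}

#' @export
print.groove_report <- function(x, ...) {
  cat(sprintf("groove_report: %s, %d case(s), %d error(s)\n", x$mode,
              x$n_cases, x$n_errors))
  if (!is.na(x$mean_rmsd))
    cat(sprintf("  mean core RMSD %.2f A, fraction correct %.2f\n",
                x$mean_rmsd, x$fraction_correct))
  invisible(x)
}

#' Write an experiment report as JSON
#'
#' Timing fields are kept; everything in the report is
#' JSON-serializable. Poses are written separately via [write_poses()].
#'
#' @param report A `groove_report`.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Scan an antigen sequence with a moving 9-mer window
#'
#' Epitope-screening helper: docks every length-`window` subsequence of
#' an antigen onto a single receptor template and returns the ranked
#' report.
#'
#' @param template A `pmhc` complex or PDB path.
#' @param antigen Antigen sequence (one-letter string) or path to a FASTA
#'   file (first record used).
#' @param window Window length (default 9).
#' @param step Window step.
#' @inheritParams run_experiment
#' @return A `groove_report` with one case per window, ranked by score;
#'   each case id is the window start.
#' @export
scan_antigen <- function(template, antigen, window = 9L, step = 1L,
                         mc = mc_params(), ff = default_forcefield(),
                         weights = scoring_weights(), refine = TRUE,
                         refine_args = list()) {
  if (file.exists(antigen)) {
    fa <- bio3d::read.fasta(antigen)
    antigen <- paste(toupper(fa$ali[1, ]), collapse = "")
    antigen <- gsub("-", "", antigen)
  }
  starts <- seq(1L, nchar(antigen) - window + 1L, by = step)
  peps <- vapply(starts, function(s) substr(antigen, s, s + window - 1L), "")
  rep <- run_experiment("single_template",
                        list(template = template, peptides = peps),
                        mc = mc, ff = ff, weights = weights,
                        refine = refine, refine_args = refine_args)
  for (i in seq_along(rep$cases)) {
    w <- match(rep$cases[[i]]$sequence, peps)
    rep$cases[[i]]$window_start <- if (!is.na(w)) starts[w] else NA_integer_
  }
  rep
}
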