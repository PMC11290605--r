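# End-to-end orchestration: simulate a full synthetic study, or analyze
# trial/gaze/isopter inputs into the standard set of output tables. The
# numbered scripts under analysis/ are thin drivers over these functions.

#' Simulate a full synthetic study to disk
#'
#' Writes the trial CSV, a per-participant gaze CSV (with a configurable set
#' of participants forced to unstable fixation), an isopter CSV, and the
#' ground-truth sidecar JSON, all derived from one seed.
#'
#' @param out_dir output directory (created if missing).
#' @param spec a [cohort_spec()]; its seed drives everything.
#' @param n_unstable number of participants (taken from the end of the
#'   cohort) given unstable gaze (default 0).
#' @param gaze_duration_s seconds of gaze per participant (default 5).
#' @param vma_young,vma_older group-mean target VMA for the isopter charts.
#' @param vma_sd between-participant SD of the VMA target (default 14,
#'   comparable to real kinetic-perimetry cohorts).
#' @return Invisibly, the list of written paths.
#' @export
run_simulation <- function(out_dir, spec = cohort_spec(), n_unstable = 0L,
                           gaze_duration_s = 5, vma_young = 20, vma_older = 33,
                           vma_sd = 14) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sim <- gen_cohort(spec)
  ids <- rownames(sim$truth$params)
  paths <- list(trials = file.path(out_dir, "trials.csv"),
                gaze = file.path(out_dir, "gaze.csv"),
                isopters = file.path(out_dir, "isopters.csv"),
                truth = file.path(out_dir, "ground_truth.json"))
  write_trials(sim$trials, paths$trials)
  write_ground_truth(sim$truth, paths$truth)

  unstable_ids <- if (n_unstable > 0L) utils::tail(ids, n_unstable) else character(0)
  gaze <- do.call(rbind, lapply(seq_along(ids), function(i) {
    stab <- if (ids[i] %in% unstable_ids) "unstable" else "stable"
    g <- gen_gaze(stab, duration_s = gaze_duration_s, seed = spec$seed + 1000L + i)
    cbind(participant_id = ids[i], block = 1L, g)
  }))
  write_gaze(gaze, paths$gaze)

  set.seed(spec$seed + 500L)
  vma_targets <- pmin(180, pmax(-180, ifelse(
    sim$truth$group == "young", vma_young, vma_older) +
      stats::rnorm(length(ids), 0, vma_sd)))
  iso <- do.call(rbind, lapply(seq_along(ids), function(i) {
    ch <- gen_isopters(vma_targets[i], seed = spec$seed + 2000L + i)
    data.frame(participant_id = ids[i], eye = ch$eye, isopter = ch$isopter,
               angle_deg = ch$angle_deg, radius_deg = ch$radius_deg)
  }))
  write_isopters(iso, paths$isopters)
  invisible(paths)
}

#' Run the full analysis chain on trial/gaze/isopter inputs
#'
#' Gaze QC first: participants grading unstable are excluded before any
#' model fitting. Then Pr group summaries, per-group aggregate MLE fits,
#' latent-trait hierarchical fits with convergence diagnostics and posterior
#' predictive checks, posterior group differences (forest-plot data), and
#' the perimetry VMA table. Every output records the seed.
#'
#' @param trials trial records (or a path read via [read_trials()]).
#' @param gaze optional gaze samples (or path); when NULL no QC exclusion.
#' @param isopters optional isopter points (or path).
#' @param out_dir output directory for the CSV/JSON artifacts.
#' @param config a [latent_config()] for the hierarchical fits.
#' @return A list with `qc`, `summary`, `mle`, `fits`, `ppp`,
#'   `differences`, `vma`, `excluded`, written to `out_dir` as files.
#' @export
run_report <- function(trials, gaze = NULL, isopters = NULL,
                       out_dir = NULL, config = latent_config()) {
  if (is.character(trials)) trials <- read_trials(trials)
  if (is.character(gaze)) gaze <- read_gaze(gaze)
  if (is.character(isopters)) isopters <- read_isopters(isopters)

  qc <- NULL
  excluded <- character(0)
  if (!is.null(gaze)) {
    qc <- gaze_qc_report(gaze)
    excluded <- qc$participant_id[qc$excluded]
    trials <- trials[!trials$participant_id %in% excluded, , drop = FALSE]
  }
  if (nrow(trials) == 0L) stop("all participants excluded by gaze QC")

  cohort <- cohort_table(trials)
  summary <- group_summary(cohort)

  groups_present <- intersect(.GROUPS, unique(cohort$group))
  mle <- lapply(stats::setNames(nm = groups_present), function(g) {
    sub <- cohort_subset(cohort, g)
    agg <- freq_table(Reduce(`+`, lapply(sub$tables, `[[`, "counts")))
    fit_mle(agg, seed = config$seed)
  })

  fits <- lapply(stats::setNames(nm = groups_present), function(g) {
    sample_posterior(cohort_subset(cohort, g), config)
  })
  ppp <- lapply(stats::setNames(nm = groups_present), function(g) {
    posterior_predictive_pvalues(fits[[g]], cohort_subset(cohort, g),
                                 seed = config$seed)
  })
  differences <- if (all(c("young", "older") %in% groups_present)) {
    group_difference(fits$young, fits$older, seed = config$seed)
  } else NULL

  vma <- if (!is.null(isopters)) vma_table(isopters) else NULL

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    if (!is.null(qc)) utils::write.csv(qc, file.path(out_dir, "gaze_qc.csv"), row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "pr_summary.csv"), row.names = FALSE)
    if (!is.null(differences)) {
      utils::write.csv(differences, file.path(out_dir, "group_differences.csv"),
                       row.names = FALSE)
    }
    if (!is.null(vma)) utils::write.csv(vma, file.path(out_dir, "vma.csv"), row.names = FALSE)
    diag <- list(
      seed = config$seed,
      mcmc = list(n_iter = config$n_iter, burn_in = config$burn_in,
                  thin = config$thin, n_chains = config$n_chains),
      excluded = as.list(excluded),
      groups = lapply(stats::setNames(nm = groups_present), function(g) {
        list(posterior_mean = as.list(colMeans(fits[[g]]$group_mean)),
             rhat = as.list(fits[[g]]$rhat),
             converged = fits[[g]]$converged,
             p_T1 = ppp[[g]]$p_T1, p_T2 = ppp[[g]]$p_T2,
             mle = as.list(unclass(mle[[g]]$params)),
             g_squared = mle[[g]]$g_squared)
      }))
    jsonlite::write_json(diag, file.path(out_dir, "diagnostics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(qc = qc, summary = summary, mle = mle, fits = fits,
                 ppp = ppp, differences = differences, vma = vma,
                 excluded = excluded))
}
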