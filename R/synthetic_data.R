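# Ground-truth synthetic data emulating the study's statistical structure:
# a two-group cohort (25 young, 20 older) completing 8 blocks with 80 up-old,
# 80 down-old and 80 new test trials per participant, responses drawn from
# the source-item MPT with probit-normal individual variation; gaze streams
# with controllable fixation stability; isopter charts with controllable
# vertical asymmetry.

#' Specification of a synthetic cohort
#'
#' Defaults are the study conditions: 25 young and 20 older participants,
#' 80 trials per tree spread over 8 blocks, and group-level parameter means
#' echoing the qualitative empirical pattern — recollection of upper-field
#' positions reduced by ~0.2 in the older group, a smaller reduction for the
#' lower field, familiarity near-preserved, and a slightly lower "old"
#' guessing rate in older adults. Individual parameters are probit-normal
#' around the group means with per-parameter SD `latent_sd` and correlation
#' `latent_corr` on the probit scale.
#'
#' @param n_young,n_older group sizes (defaults 25 and 20).
#' @param trials_per_tree test trials per tree per participant (default 80).
#' @param group_means named list of [mpt_params()] for `young` and `older`.
#' @param latent_sd per-parameter probit-scale SD (scalar or length 6,
#'   default 0.4).
#' @param latent_corr 6x6 correlation matrix (default exchangeable 0.2).
#' @param miss_rate per-trial probability of a missed item response; scalar
#'   or named per group (default 0.02).
#' @param n_blocks number of blocks (default 8).
#' @param seed integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_young = 25L, n_older = 20L, trials_per_tree = 80L,
                        group_means = list(
                          young = mpt_params(S_up = 0.60, S_down = 0.62,
                                             I_up = 0.48, I_down = 0.52,
                                             o = 0.26, g = 0.55),
                          older = mpt_params(S_up = 0.40, S_down = 0.47,
                                             I_up = 0.44, I_down = 0.50,
                                             o = 0.20, g = 0.50)),
                        latent_sd = 0.4,
                        latent_corr = NULL,
                        miss_rate = 0.02,
                        n_blocks = 8L, seed = 1L) {
  if (n_young < 1L || n_older < 1L) stop("each group needs at least one participant")
  if (is.null(latent_corr)) {
    latent_corr <- matrix(0.2, 6L, 6L); diag(latent_corr) <- 1
  }
  if (!isSymmetric(unname(latent_corr)) ||
      any(eigen(latent_corr, symmetric = TRUE, only.values = TRUE)$values <= 1e-10)) {
    stop("latent_corr must be a symmetric positive-definite correlation matrix")
  }
  if (length(latent_sd) == 1L) latent_sd <- rep(latent_sd, 6L)
  if (length(miss_rate) == 1L && is.null(names(miss_rate))) {
    miss_rate <- c(young = unname(miss_rate), older = unname(miss_rate))
  }
  structure(list(n_young = as.integer(n_young), n_older = as.integer(n_older),
                 trials_per_tree = as.integer(trials_per_tree),
                 group_means = lapply(group_means, as_mpt_params),
                 latent_sd = latent_sd, latent_corr = latent_corr,
                 miss_rate = miss_rate, n_blocks = as.integer(n_blocks),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

gcd2 <- function(a, b) if (b == 0L) a else gcd2(b, a %% b)

# spread n trials as evenly as possible over k blocks
spread_blocks <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  base + as.integer(seq_len(k) <= extra)
}

#' Generate a synthetic cohort of trial records with ground truth
#'
#' Per participant: a probit-scale latent vector is drawn from the group
#' multivariate normal and mapped through the standard normal CDF to MPT
#' parameters; each tree's trials are drawn from the model's category
#' probabilities; an independent Bernoulli miss process then blanks item
#' responses. Reaction-time fields are filled with placeholder lognormal
#' draws and are not analyzed.
#'
#' @param spec a [cohort_spec()].
#' @return A list with `trials` (trial-record `data.frame`) and `truth`
#'   (class `ground_truth`): per-participant true parameters, expected
#'   post-miss counts, group assignment, the spec and seed.
#' @export
gen_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  # delta = D * C^{1/2} z with D = diag(latent_sd): per-parameter SDs of
  # zero are allowed (degenerate, no individual variation on that axis)
  L <- chol(spec$latent_corr)
  groups <- c(rep("young", spec$n_young), rep("older", spec$n_older))
  ids <- sprintf("p%03d", seq_along(groups))
  trials_list <- vector("list", length(ids))
  true_params <- matrix(NA_real_, length(ids), 6L,
                        dimnames = list(ids, .PARAM_NAMES))
  count_tables <- vector("list", length(ids)); names(count_tables) <- ids

  n_tree <- spec$trials_per_tree
  per_block <- spread_blocks(n_tree, spec$n_blocks)
  item_counter <- 0L

  for (i in seq_along(ids)) {
    g <- groups[i]
    mu_probit <- stats::qnorm(unclass(spec$group_means[[g]]))
    theta <- stats::pnorm(mu_probit +
                            spec$latent_sd * drop(crossprod(L, stats::rnorm(6L))))
    true_params[i, ] <- theta
    probs <- category_probabilities(as_mpt_params(theta))

    rows <- vector("list", 3L)
    for (t in seq_along(.TREES)) {
      draw <- sample.int(3L, n_tree, replace = TRUE, prob = probs[t, ])
      missed <- stats::runif(n_tree) < spec$miss_rate[[g]]
      position <- c("up", "down", "new")[t]
      item_response <- ifelse(missed, "miss",
                              c("old", "old", "new")[draw])
      source_response <- ifelse(item_response == "old",
                                c("up", "down", "")[draw], "none")
      rt_item <- ifelse(item_response == "miss", NA_real_,
                        round(stats::rlnorm(n_tree, log(1.0), 0.35), 4L))
      rt_source <- ifelse(item_response == "old",
                          round(stats::rlnorm(n_tree, log(0.8), 0.40), 4L),
                          NA_real_)
      item_ids <- sprintf("itm%05d", item_counter + seq_len(n_tree))
      item_counter <- item_counter + n_tree
      rows[[t]] <- data.frame(
        participant_id = ids[i], group = g,
        block = rep(seq_len(spec$n_blocks), times = per_block),
        item_id = item_ids, true_position = position,
        item_response = item_response, source_response = source_response,
        rt_item = rt_item, rt_source = rt_source,
        stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    # shuffle within block so trial order carries no tree structure
    df <- df[order(df$block, stats::runif(nrow(df))), , drop = FALSE]
    trials_list[[i]] <- df

    answered <- df$item_response != "miss"
    tree <- factor(c(up = "UP", down = "DOWN", new = "NEW")[df$true_position[answered]], .TREES)
    cat_ <- factor(ifelse(df$item_response[answered] == "new", "new",
                          ifelse(df$source_response[answered] == "up",
                                 "old_up", "old_down")), .CATEGORIES)
    count_tables[[i]] <- unclass(table(tree, cat_))
  }
  trials <- do.call(rbind, trials_list)
  rownames(trials) <- NULL
  validate_trials(trials)
  truth <- structure(list(params = true_params, counts = count_tables,
                          group = stats::setNames(groups, ids),
                          spec = spec, seed = spec$seed),
                     class = "ground_truth")
  list(trials = trials, truth = truth)
}

#' Write the ground truth of a synthetic cohort to JSON
#'
#' Sidecar file holding the generator seed, the generating group means, and
#' each participant's true parameters, so any downstream estimate can be
#' compared against truth.
#'
#' @param truth a `ground_truth` object from [gen_cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- list(
    seed = truth$seed,
    group_means = lapply(truth$spec$group_means, function(p) as.list(unclass(p))),
    participants = lapply(rownames(truth$params), function(id) {
      list(id = id, group = unname(truth$group[[id]]),
           params = as.list(truth$params[id, ]))
    }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Generate a synthetic gaze stream of known fixation stability
#'
#' Builds a 1000-Hz stream of `n_epochs` still epochs with Gaussian jitter,
#' separated by fast (3-sample) position jumps that register as saccades
#' under the default velocity-threshold settings. Epoch centers are placed
#' at radii chosen so that the centroid pattern classifies into the
#' requested Fujii category: `stable` (90% of epochs within 2 degrees),
#' `relatively_unstable` (60% within 2 degrees, all within 4),
#' `unstable` (only 60% within 4 degrees).
#'
#' @param stability `"stable"`, `"relatively_unstable"`, or `"unstable"`.
#' @param duration_s stream duration in seconds (>= 2 when `n_epochs > 1`).
#' @param seed integer seed.
#' @param center fixation-target coordinates (degrees).
#' @param jitter within-epoch positional jitter SD in degrees (default 0.02).
#' @param n_epochs number of still epochs (default 10; with 1, a single
#'   still epoch at the center is produced).
#' @return A gaze `data.frame` with columns `t_ms`, `x_deg`, `y_deg`.
#' @export
gen_gaze <- function(stability = c("stable", "relatively_unstable", "unstable"),
                     duration_s = 5, seed = 1L, center = c(0, 0),
                     jitter = 0.02, n_epochs = 10L) {
  stability <- match.arg(stability)
  if (duration_s <= 0) stop("duration must be positive")
  if (n_epochs > 1L && duration_s < 2) {
    stop("need at least 2 s to place ", n_epochs, " distinguishable epochs")
  }
  set.seed(seed)
  n_total <- round(duration_s * 1000)
  if (n_epochs == 1L) {
    radii <- 0
  } else {
    radii <- switch(stability,
      stable = c(rep(0.3, ceiling(0.9 * n_epochs)),
                 rep(3.0, n_epochs - ceiling(0.9 * n_epochs))),
      relatively_unstable = c(rep(0.5, ceiling(0.6 * n_epochs)),
                              rep(3.0, n_epochs - ceiling(0.6 * n_epochs))),
      unstable = c(rep(1.0, ceiling(0.6 * n_epochs)),
                   rep(6.0, n_epochs - ceiling(0.6 * n_epochs))))
  }
  angles <- 2 * pi * (seq_along(radii) - 1L) / max(1L, length(radii))
  # visit epochs in a long-stride order so consecutive centers are far
  # apart: each inter-epoch jump is a genuine saccade-sized step
  ne <- length(radii)
  stride <- max(1L, ne %/% 2L)
  while (stride > 1L && gcd2(stride, ne) != 1L) stride <- stride - 1L
  ord <- ((seq_len(ne) - 1L) * stride) %% ne + 1L
  cx <- (center[1L] + radii * cos(angles))[ord]
  cy <- (center[2L] + radii * sin(angles))[ord]

  n_still <- spread_blocks(n_total, n_epochs)
  x <- numeric(0); y <- numeric(0)
  for (e in seq_len(n_epochs)) {
    x <- c(x, cx[e] + stats::rnorm(n_still[e], 0, jitter))
    y <- c(y, cy[e] + stats::rnorm(n_still[e], 0, jitter))
  }
  data.frame(t_ms = seq_along(x) - 1, x_deg = x, y_deg = y)
}

#' Generate a synthetic isopter chart with a target vertical asymmetry
#'
#' Builds a roughly circular isopter whose lower-hemifield radii are scaled
#' relative to the upper so that the polygonal hemifield areas reproduce the
#' requested VMA. After optional radial jitter is applied, the lower-half
#' scale is calibrated by bisection against [hemifield_areas()], so the
#' achieved VMA matches the target to well within 1 at the default sampling
#' density.
#'
#' @param target_vma requested VMA, `|target| < 200`.
#' @param base_radius nominal radius in degrees (default 50).
#' @param seed integer seed for the radial jitter.
#' @param n_points sampled meridians (default 24, offset from 0/180).
#' @param jitter_sd radial jitter SD in degrees (default 0.5).
#' @param eye,isopter chart labels.
#' @return An [isopter_chart()].
#' @export
gen_isopters <- function(target_vma, base_radius = 50, seed = 1L,
                         n_points = 24L, jitter_sd = 0.5,
                         eye = "right", isopter = "V1e") {
  if (abs(target_vma) >= 200) stop("infeasible target VMA (|vma| must be < 200)")
  set.seed(seed)
  step <- 360 / n_points
  angles <- step / 2 + step * (seq_len(n_points) - 1L)
  upper <- angles > 0 & angles < 180
  radii <- base_radius + stats::rnorm(n_points, 0, jitter_sd)
  radii <- pmax(radii, base_radius * 0.5)

  vma_at <- function(s) {
    r <- radii
    r[!upper] <- r[!upper] * s
    ch <- isopter_chart(eye, isopter, angles, r)
    ar <- hemifield_areas(ch)
    vma_index(ar$upper_area, ar$lower_area)$vma
  }
  lo <- 0.1; hi <- 10
  if (vma_at(lo) > target_vma || vma_at(hi) < target_vma) {
    stop("target VMA not reachable by hemifield scaling")
  }
  for (k in seq_len(200L)) {
    mid <- sqrt(lo * hi)
    if (vma_at(mid) < target_vma) lo <- mid else hi <- mid
    if (abs(vma_at(mid) - target_vma) < 1e-6) break
  }
  s <- sqrt(lo * hi)
  r <- radii
  r[!upper] <- r[!upper] * s
  isopter_chart(eye, isopter, angles, r)
}

#' Write gaze samples / isopter points to their CSV dialects
#'
#' @param gaze gaze samples with `participant_id` and `block` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gaze <- function(gaze, path) {
  utils::write.csv(gaze[, c("participant_id", "block", "t_ms", "x_deg", "y_deg")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gaze
#' @param points isopter point `data.frame` with columns
#'   `participant_id, eye, isopter, angle_deg, radius_deg`.
#' @export
write_isopters <- function(points, path) {
  utils::write.csv(points[, c("participant_id", "eye", "isopter",
                              "angle_deg", "radius_deg")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
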