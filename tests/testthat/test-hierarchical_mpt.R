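# Desk-scale checks of the latent-trait sampler; full-scale recovery runs
# live in the acceptance tests.

small_cohort <- function(n_per_group = 4L, trials = 40L, seed = 51L,
                         latent_sd = 0.2) {
  sim <- gen_cohort(cohort_spec(n_young = n_per_group, n_older = n_per_group,
                                trials_per_tree = trials,
                                latent_sd = latent_sd, miss_rate = 0,
                                seed = seed))
  cohort_table(sim$trials)
}

test_that("probit transform round-trips and draws stay on the probability scale", {
  x <- seq(-6, 6, length.out = 200)
  # log-scale round trip is tail-accurate across the whole range
  expect_lt(max(abs(probit(inv_probit(x, log_p = TRUE), log_p = TRUE) - x)),
            1e-12)
  # raw probability scale: exact where doubles can represent the tail
  # (spacing of doubles near p = 1 caps the upper tail at ~1e-8)
  neg <- x[x <= 0]
  expect_lt(max(abs(probit(inv_probit(neg)) - neg)), 1e-12)
  expect_lt(max(abs(probit(inv_probit(x)) - x)), 1e-7)
  # probability -> probit -> probability is well-conditioned everywhere
  p <- seq(1e-9, 1 - 1e-9, length.out = 200)
  expect_lt(max(abs(inv_probit(probit(p)) - p)), 1e-14)

  cohort <- cohort_subset(small_cohort(), "young")
  cfg <- latent_config(n_iter = 300L, burn_in = 100L, thin = 2L,
                       n_chains = 2L, seed = 7L)
  dr <- sample_posterior(cohort, cfg)
  expect_true(all(dr$group_mean >= 0 & dr$group_mean <= 1))
  expect_true(all(dr$indiv >= 0 & dr$indiv <= 1))
  # draw bookkeeping: chains x (n_iter - burn_in) / thin
  expect_equal(nrow(dr$group_mean), 2L * (300L - 100L) / 2L)
  expect_equal(dr$chain, rep(1:2, each = 100L))
})

test_that("identical config and seed give identical draws", {
  cohort <- cohort_subset(small_cohort(), "older")
  cfg <- latent_config(n_iter = 250L, burn_in = 50L, thin = 2L,
                       n_chains = 2L, seed = 13L)
  d1 <- sample_posterior(cohort, cfg)
  d2 <- sample_posterior(cohort, cfg)
  expect_identical(d1$group_mean, d2$group_mean)
  expect_identical(d1$indiv, d2$indiv)
  expect_identical(d1$rhat, d2$rhat)
})

test_that("split R-hat flags separated chains and passes mixed ones", {
  set.seed(2)
  mixed <- matrix(rnorm(4000), ncol = 2)
  expect_lt(split_rhat(mixed), 1.05)
  separated <- cbind(rnorm(2000), rnorm(2000) + 3)
  expect_gt(split_rhat(separated), 1.5)
  # within-chain drift registers too (that is the point of splitting)
  drift <- cbind(seq(0, 3, length.out = 2000) + rnorm(2000, 0, 0.1),
                 seq(0, 3, length.out = 2000) + rnorm(2000, 0, 0.1))
  expect_gt(split_rhat(drift), 1.05)
})

test_that("a zero-variance cohort concentrates on the aggregate moment estimate", {
  # all participants share one frequency table with large counts
  probs <- category_probabilities(mpt_params(0.6, 0.55, 0.45, 0.5, 0.25, 0.55))
  counts <- round(probs * 4000)
  trials_per_tree <- unique(rowSums(counts))
  tables <- lapply(1:6, function(i) freq_table(counts))
  names(tables) <- sprintf("p%03d", 1:6)
  cohort <- structure(list(tables = tables,
                           group = setNames(rep("young", 6), names(tables)),
                           covariate = NULL),
                      class = "cohort_table")
  agg <- freq_table(Reduce(`+`, lapply(tables, `[[`, "counts")))
  me <- moment_estimator(agg)$params

  cfg <- latent_config(n_iter = 1500L, burn_in = 500L, thin = 2L,
                       n_chains = 2L, seed = 3L)
  dr <- sample_posterior(cohort, cfg)
  expect_equal(unname(colMeans(dr$group_mean)), unname(unclass(me)),
               tolerance = 0.05)
})

test_that("group differences behave under identity and translation", {
  cohort <- cohort_subset(small_cohort(), "young")
  cfg <- latent_config(n_iter = 300L, burn_in = 100L, thin = 2L,
                       n_chains = 2L, seed = 5L)
  dr <- sample_posterior(cohort, cfg)

  gd0 <- group_difference(dr, dr, seed = 1L)
  expect_equal(gd0$mean, rep(0, 6), tolerance = 1e-12)
  expect_false(any(gd0$excludes_zero))

  shifted <- dr
  shifted$group_mean <- dr$group_mean - 0.07
  gd <- group_difference(dr, shifted, seed = 1L)
  expect_equal(gd$mean, rep(0.07, 6), tolerance = 1e-12)
  expect_true(all(gd$lower <= gd$mean & gd$mean <= gd$upper))

  # draw-count mismatch resolves by seeded subsampling of the longer set
  longer <- dr
  longer$group_mean <- rbind(dr$group_mean, dr$group_mean)
  gd2 <- group_difference(longer, dr, seed = 2L)
  expect_equal(nrow(dr$group_mean), 200L)
  expect_true(all(is.finite(gd2$mean)))
})

test_that("posterior predictive checks demand enough draws and detect misfit", {
  cohort <- cohort_subset(small_cohort(), "young")
  cfg <- latent_config(n_iter = 300L, burn_in = 200L, thin = 10L,
                       n_chains = 2L, seed = 5L)
  dr <- sample_posterior(cohort, cfg)
  expect_error(suppressWarnings(posterior_predictive_pvalues(dr, cohort)),
               "100 usable draws")

  # grossly inconsistent counts: the mean-structure check must fail.
  # NEW-tree false alarms say source guessing favors "up" (g ~ 0.86), yet
  # up-old items are overwhelmingly attributed "down": the algebraic
  # inversion gives S_up far below 0, so no parameter vector reproduces
  # these mean frequencies.
  bad_counts <- ft9(c(10, 60, 10, 60, 10, 10, 60, 10, 10))
  tables <- lapply(1:6, function(i) bad_counts)
  names(tables) <- sprintf("q%03d", 1:6)
  bad_cohort <- structure(list(tables = tables,
                               group = setNames(rep("young", 6), names(tables)),
                               covariate = NULL),
                          class = "cohort_table")
  cfg2 <- latent_config(n_iter = 900L, burn_in = 300L, thin = 2L,
                        n_chains = 2L, seed = 11L)
  dr2 <- sample_posterior(bad_cohort, cfg2)
  pp <- suppressWarnings(
    posterior_predictive_pvalues(dr2, bad_cohort, seed = 3L))
  expect_lt(pp$p_T1, 0.05)
})

test_that("95% intervals for group means cover truth across seeded replications", {
  # 20 reduced-size replications; a loose >= 80% pooled coverage bound
  truth <- c(S_up = 0.6, S_down = 0.62, I_up = 0.48, I_down = 0.52,
             o = 0.26, g = 0.55)
  hits <- 0L; total <- 0L
  for (rep_seed in 1:20) {
    sim <- gen_cohort(cohort_spec(n_young = 8L, n_older = 1L,
                                  trials_per_tree = 40L, latent_sd = 0.15,
                                  miss_rate = 0, seed = 100L + rep_seed))
    cohort <- cohort_subset(cohort_table(sim$trials), "young")
    cfg <- latent_config(n_iter = 700L, burn_in = 300L, thin = 2L,
                         n_chains = 2L, seed = rep_seed)
    dr <- sample_posterior(cohort, cfg)
    q <- apply(dr$group_mean, 2L, stats::quantile, c(0.025, 0.975))
    hits <- hits + sum(q[1L, ] <= truth & truth <= q[2L, ])
    total <- total + 6L
  }
  expect_gte(hits / total, 0.8)
})

test_that("the sex covariate shifts latent means additively on the probit scale", {
  sim <- gen_cohort(cohort_spec(n_young = 6L, n_older = 1L,
                                trials_per_tree = 40L, latent_sd = 0.2,
                                miss_rate = 0, seed = 77L))
  ids <- unique(sim$trials$participant_id)
  cov <- setNames(rep(c(0, 1), length.out = length(ids)), ids)
  cohort <- cohort_subset(cohort_table(sim$trials, covariates = cov), "young")
  cfg <- latent_config(n_iter = 300L, burn_in = 100L, thin = 2L,
                       n_chains = 2L, seed = 3L, use_covariate = TRUE)
  dr <- sample_posterior(cohort, cfg)
  expect_false(is.null(dr$beta))
  expect_equal(dim(dr$beta), c(200L, 6L))
  # without a covariate in the cohort, requesting one errors
  plain <- cohort_subset(cohort_table(sim$trials), "young")
  expect_error(sample_posterior(plain, cfg), "covariate")
})
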