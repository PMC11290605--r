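# Latent-trait hierarchical Bayesian estimation of the source-item MPT.
#
# Participant i's parameter p obeys
#     theta_ip = Phi(mu_p + beta_p * x_i + xi_p * eta_ip),
#     eta_i ~ MVN(0, Q),
# with Phi the standard normal CDF. The implied covariance of the probit-
# scale individual effects is Sigma = diag(xi) Q diag(xi): a scaled
# inverse-Wishart prior (Q ~ IW(I, P+1), xi_p ~ U(0, 10)), the standard
# weakly-informative latent-trait default, which keeps the Q update
# conjugate while the scale factors absorb the IW prior's variance bias.
# mu_p (and beta_p, when a covariate is supplied) carry standard-normal
# priors on the probit scale.
#
# Sampling is Metropolis-within-Gibbs: conjugate inverse-Wishart update for
# Q given eta; adaptive random-walk Metropolis for mu, beta, xi and eta
# (adaptation frozen after burn-in so the post-burn-in chain is Markovian).

#' Probit and inverse-probit transforms
#'
#' The latent-trait model lives on the probit scale; these are the forward
#' and inverse maps. With `log_p = TRUE` the probability is carried on the
#' log scale, which keeps the round-trip accurate to ~1e-15 across (-6, 6);
#' on the raw probability scale, double precision near p = 1 limits the
#' upper-tail round-trip to ~1e-8 regardless of algorithm.
#'
#' @param p probability (or log-probability with `log_p = TRUE`).
#' @param x probit-scale value.
#' @param log_p carry probabilities on the log scale.
#' @return `probit()`: probit-scale value; `inv_probit()`: (log-)probability.
#' @export
probit <- function(p, log_p = FALSE) stats::qnorm(p, log.p = log_p)

#' @rdname probit
#' @export
inv_probit <- function(x, log_p = FALSE) stats::pnorm(x, log.p = log_p)

#' Configuration for the latent-trait hierarchical sampler
#'
#' Defaults mirror the study-scale MCMC settings: 50,000 iterations with a
#' 10,000-sample burn-in and a thinning factor of 10; convergence is judged
#' by split R-hat < 1.05. At least two chains are required so that R-hat is
#' meaningful. Reduced settings (e.g. 5,000/1,000/5) are appropriate for
#' desk-scale recovery runs.
#'
#' @param n_iter MCMC iterations per chain (default 50000).
#' @param burn_in burn-in iterations discarded per chain (default 10000).
#' @param thin thinning factor (default 10).
#' @param n_chains number of chains, >= 2 (default 2).
#' @param rhat_threshold convergence bound on split R-hat (default 1.05).
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @param xi_upper upper bound of the uniform prior on the scale factors.
#' @param use_covariate include the cohort covariate as an additive
#'   probit-scale shift on the latent means (default FALSE).
#' @return A list of class `latent_config`.
#' @export
latent_config <- function(n_iter = 50000L, burn_in = 10000L, thin = 10L,
                          n_chains = 2L, rhat_threshold = 1.05, seed = 1L,
                          xi_upper = 10, use_covariate = FALSE) {
  stopifnot(burn_in < n_iter, thin >= 1L, n_chains >= 2L)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 rhat_threshold = rhat_threshold, seed = as.integer(seed),
                 xi_upper = xi_upper, use_covariate = use_covariate),
            class = "latent_config")
}

# Vectorized category probabilities: theta is n x 6 (columns .PARAM_NAMES),
# returns n x 9 in .CAT9 order. Mirrors category_probabilities() row-wise.
vec_category_probs <- function(theta) {
  S_up <- theta[, 1L]; S_down <- theta[, 2L]
  I_up <- theta[, 3L]; I_down <- theta[, 4L]
  o <- theta[, 5L]; g <- theta[, 6L]
  cbind(
    S_up + (1 - S_up) * I_up * g + (1 - S_up) * (1 - I_up) * o * g,
    (1 - S_up) * I_up * (1 - g) + (1 - S_up) * (1 - I_up) * o * (1 - g),
    (1 - S_up) * (1 - I_up) * (1 - o),
    (1 - S_down) * I_down * g + (1 - S_down) * (1 - I_down) * o * g,
    S_down + (1 - S_down) * I_down * (1 - g) +
      (1 - S_down) * (1 - I_down) * o * (1 - g),
    (1 - S_down) * (1 - I_down) * (1 - o),
    o * g, o * (1 - g), 1 - o
  )
}

# Flatten a cohort's frequency tables into an n x 9 count matrix.
cohort_counts <- function(cohort) {
  m <- t(vapply(cohort$tables, function(ft) as.vector(t(ft$counts)),
                numeric(9L)))
  colnames(m) <- .CAT9
  m
}

# Per-participant multinomial log-likelihood kernel given theta (n x 6).
vec_loglik <- function(counts, theta) {
  probs <- vec_category_probs(theta)
  probs <- pmax(probs, 1e-300)
  rowSums(counts * log(probs))
}

run_one_chain <- function(counts, x, cfg, chain_seed) {
  n <- nrow(counts)
  P <- 6L
  set.seed(chain_seed)

  # initial values: probit of lightly-shrunk aggregate moment estimates
  agg <- freq_table(matrix(colSums(counts), 3L, 3L, byrow = TRUE))
  mu <- tryCatch(stats::qnorm(pmin(0.95, pmax(0.05, unclass(moment_estimator(agg)$params)))),
                 error = function(e) rep(0, P))
  beta <- rep(0, P)
  eta <- matrix(0, n, P)
  xi <- rep(1, P)
  Q <- diag(P)
  Omega <- diag(P)

  s_mu <- rep(0.1, P); s_beta <- rep(0.1, P)
  s_eta <- rep(0.3, P); s_xi <- rep(0.2, P)
  acc_mu <- rep(0, P); acc_beta <- rep(0, P)
  acc_eta <- rep(0, P); acc_xi <- rep(0, P)
  n_adapt_win <- 50L

  use_cov <- cfg$use_covariate && !is.null(x)
  if (!use_cov) x <- rep(0, n)

  theta_lin <- function() {
    sweep(eta, 2L, xi, `*`) +
      matrix(mu, n, P, byrow = TRUE) +
      outer(x, beta)
  }
  theta <- stats::pnorm(theta_lin())
  ll <- vec_loglik(counts, theta)

  keep_iters <- seq.int(cfg$burn_in + cfg$thin, cfg$n_iter, by = cfg$thin)
  n_keep <- length(keep_iters)
  group_mean_draws <- matrix(NA_real_, n_keep, P,
                             dimnames = list(NULL, .PARAM_NAMES))
  mu_draws <- matrix(NA_real_, n_keep, P, dimnames = list(NULL, .PARAM_NAMES))
  beta_draws <- if (use_cov) matrix(NA_real_, n_keep, P, dimnames = list(NULL, .PARAM_NAMES)) else NULL
  indiv_draws <- array(NA_real_, c(n_keep, n, P),
                       dimnames = list(NULL, rownames(counts), .PARAM_NAMES))
  k <- 0L

  for (iter in seq_len(cfg$n_iter)) {
    lin <- theta_lin()

    # mu updates (one scalar RW per parameter; likelihood over all subjects)
    for (p in seq_len(P)) {
      prop <- mu[p] + stats::rnorm(1L, 0, s_mu[p])
      lin_p <- lin[, p] + (prop - mu[p])
      theta_prop <- theta
      theta_prop[, p] <- stats::pnorm(lin_p)
      ll_prop <- vec_loglik(counts, theta_prop)
      log_r <- sum(ll_prop - ll) + 0.5 * (mu[p]^2 - prop^2)
      if (log(stats::runif(1L)) < log_r) {
        mu[p] <- prop; lin[, p] <- lin_p; theta <- theta_prop; ll <- ll_prop
        acc_mu[p] <- acc_mu[p] + 1
      }
    }

    # beta updates (covariate slope), same scheme
    if (use_cov) {
      for (p in seq_len(P)) {
        prop <- beta[p] + stats::rnorm(1L, 0, s_beta[p])
        lin_p <- lin[, p] + (prop - beta[p]) * x
        theta_prop <- theta
        theta_prop[, p] <- stats::pnorm(lin_p)
        ll_prop <- vec_loglik(counts, theta_prop)
        log_r <- sum(ll_prop - ll) + 0.5 * (beta[p]^2 - prop^2)
        if (log(stats::runif(1L)) < log_r) {
          beta[p] <- prop; lin[, p] <- lin_p; theta <- theta_prop; ll <- ll_prop
          acc_beta[p] <- acc_beta[p] + 1
        }
      }
    }

    # eta updates: component p for all participants at once, accepted
    # per participant (they are conditionally independent given mu, Q, xi)
    for (p in seq_len(P)) {
      prop <- eta[, p] + stats::rnorm(n, 0, s_eta[p])
      lin_p <- lin[, p] + xi[p] * (prop - eta[, p])
      theta_prop <- theta
      theta_prop[, p] <- stats::pnorm(lin_p)
      ll_prop <- vec_loglik(counts, theta_prop)
      # conditional MVN prior term for component p given the others
      cross <- eta %*% Omega[, p] - Omega[p, p] * eta[, p]
      d_prior <- -0.5 * Omega[p, p] * (prop^2 - eta[, p]^2) -
        (prop - eta[, p]) * cross
      accept <- log(stats::runif(n)) < (ll_prop - ll + d_prior)
      if (any(accept)) {
        eta[accept, p] <- prop[accept]
        lin[accept, p] <- lin_p[accept]
        theta[accept, p] <- theta_prop[accept, p]
        ll[accept] <- ll_prop[accept]
        acc_eta[p] <- acc_eta[p] + mean(accept)
      }
    }

    # xi updates (scale factors, uniform prior): global accept per parameter
    for (p in seq_len(P)) {
      prop <- xi[p] + stats::rnorm(1L, 0, s_xi[p])
      if (prop <= 0 || prop >= cfg$xi_upper) next
      lin_p <- lin[, p] + (prop - xi[p]) * eta[, p]
      theta_prop <- theta
      theta_prop[, p] <- stats::pnorm(lin_p)
      ll_prop <- vec_loglik(counts, theta_prop)
      log_r <- sum(ll_prop - ll)
      if (log(stats::runif(1L)) < log_r) {
        xi[p] <- prop; lin[, p] <- lin_p; theta <- theta_prop; ll <- ll_prop
        acc_xi[p] <- acc_xi[p] + 1
      }
    }

    # conjugate inverse-Wishart update for Q given eta
    S_post <- diag(P) + crossprod(eta)
    df_post <- (P + 1L) + n
    W <- stats::rWishart(1L, df_post, solve(S_post))[, , 1L]
    Q <- solve(W)
    if (any(!is.finite(Q))) stop("degenerate covariance update (non-finite Q)")
    Omega <- W

    # adapt proposal scales during burn-in only
    if (iter <= cfg$burn_in && iter %% n_adapt_win == 0L) {
      tune <- function(s, acc, target = 0.44) {
        rate <- acc / n_adapt_win
        s * exp(pmin(0.5, pmax(-0.5, rate - target)))
      }
      s_mu <- tune(s_mu, acc_mu); s_beta <- tune(s_beta, acc_beta)
      s_eta <- tune(s_eta, acc_eta); s_xi <- tune(s_xi, acc_xi)
      acc_mu[] <- 0; acc_beta[] <- 0; acc_eta[] <- 0; acc_xi[] <- 0
    }

    if (iter > cfg$burn_in && (iter - cfg$burn_in) %% cfg$thin == 0L) {
      k <- k + 1L
      group_mean_draws[k, ] <- stats::pnorm(mu)
      mu_draws[k, ] <- mu
      if (use_cov) beta_draws[k, ] <- beta
      indiv_draws[k, , ] <- theta
    }
  }
  list(group_mean = group_mean_draws, mu = mu_draws, beta = beta_draws,
       indiv = indiv_draws)
}

#' Sample the latent-trait hierarchical MPT posterior for one group
#'
#' Runs `cfg$n_chains` Metropolis-within-Gibbs chains (see the file header
#' for the model) and returns thinned post-burn-in draws together with
#' split R-hat per parameter on the probability-scale group means
#' `Phi(mu_p)`. A result with any R-hat above the threshold is returned
#' flagged, not discarded.
#'
#' @param cohort a single-group [cohort_table()] with >= 2 participants.
#' @param cfg a [latent_config()].
#' @return An object of class `posterior_draws`: `group_mean` (draws x 6,
#'   probability scale), `mu` (probit scale), `beta` (or NULL), `indiv`
#'   (draws x participants x 6), `chain` (chain index per draw), `rhat`
#'   (per parameter), `converged` (logical), `config`, `participants`.
#' @export
sample_posterior <- function(cohort, cfg = latent_config()) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (length(cohort$tables) < 2L) stop("need >= 2 participants")
  counts <- cohort_counts(cohort)
  x <- if (cfg$use_covariate) {
    if (is.null(cohort$covariate)) stop("config requests a covariate but the cohort has none")
    as.numeric(cohort$covariate)
  } else NULL

  chains <- lapply(seq_len(cfg$n_chains), function(c) {
    run_one_chain(counts, x, cfg, chain_seed = cfg$seed + c - 1L)
  })
  n_keep <- nrow(chains[[1L]]$group_mean)
  group_mean <- do.call(rbind, lapply(chains, `[[`, "group_mean"))
  mu <- do.call(rbind, lapply(chains, `[[`, "mu"))
  beta <- if (cfg$use_covariate) do.call(rbind, lapply(chains, `[[`, "beta")) else NULL
  indiv <- do.call(abind1, lapply(chains, `[[`, "indiv"))
  chain <- rep(seq_len(cfg$n_chains), each = n_keep)

  rhat <- apply(array(group_mean, c(n_keep, cfg$n_chains, 6L)), 3L, split_rhat)
  names(rhat) <- .PARAM_NAMES
  structure(list(group_mean = group_mean, mu = mu, beta = beta,
                 indiv = indiv, chain = chain, rhat = rhat,
                 converged = all(rhat < cfg$rhat_threshold, na.rm = TRUE),
                 config = cfg, participants = rownames(counts)),
            class = "posterior_draws")
}

# rbind along the first margin of 3-d arrays
abind1 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1L]])
  out <- array(NA_real_, c(sum(vapply(arrs, function(a) dim(a)[1L], 0)), d[2L], d[3L]),
               dimnames = c(list(NULL), dimnames(arrs[[1L]])[-1L]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1L]), , ] <- a
    at <- at + dim(a)[1L]
  }
  out
}

#' Split R-hat (potential scale reduction factor)
#'
#' Gelman-Rubin diagnostic with each chain split in half, so within-chain
#' drift also registers. Values near 1 indicate the chains have mixed;
#' < 1.05 is the conventional convergence bound here.
#'
#' @param draws matrix of draws, iterations x chains.
#' @return The split R-hat, or `NA` when variance degenerates to zero.
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- floor(n / 2L)
  if (half < 2L) return(NA_real_)
  splits <- do.call(cbind, lapply(seq_len(ncol(draws)), function(j) {
    cbind(draws[seq_len(half), j], draws[half + seq_len(half), j])
  }))
  m <- ncol(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2L, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W <= 0) return(NA_real_)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("Latent-trait MPT posterior:", nrow(x$group_mean), "draws,",
      x$config$n_chains, "chains,", length(x$participants), "participants\n")
  est <- colMeans(x$group_mean)
  q <- apply(x$group_mean, 2L, stats::quantile, c(0.025, 0.975))
  out <- data.frame(mean = est, lower95 = q[1L, ], upper95 = q[2L, ],
                    rhat = x$rhat)
  print(round(out, 3L))
  if (!x$converged) cat("WARNING: not all split R-hat below threshold\n")
  invisible(x)
}

#' Posterior predictive p-values for mean frequencies (T1) and covariance (T2)
#'
#' For each retained posterior draw, a replicate cohort is simulated from the
#' individual-level parameters. T1 is the summed squared deviation between a
#' dataset's mean category-frequency vector and its posterior-expected value;
#' T2 is the summed squared deviation between a dataset's across-participant
#' covariance matrix of category frequencies and the model-implied covariance
#' (between-participant covariance of expected frequencies plus the mean
#' within-participant multinomial covariance). Each p-value is the fraction
#' of draws in which the replicate statistic is at least the observed one;
#' values above 0.05 indicate the model accounts well for the data.
#'
#' @param draws a `posterior_draws` object.
#' @param cohort the [cohort_table()] the posterior was fit to.
#' @param seed RNG seed for the replicate simulations.
#' @return A list with `p_T1`, `p_T2`, and the per-draw statistics.
#' @export
posterior_predictive_pvalues <- function(draws, cohort, seed = 1L) {
  stopifnot(inherits(draws, "posterior_draws"), inherits(cohort, "cohort_table"))
  if (!draws$converged) {
    warning("posterior not flagged as converged; predictive p-values may be unreliable")
  }
  obs <- cohort_counts(cohort)
  n <- nrow(obs)
  n_draws <- dim(draws$indiv)[1L]
  if (n_draws < 100L) stop("need at least 100 usable draws, got ", n_draws)
  tree_n <- cbind(rowSums(obs[, 1:3, drop = FALSE]),
                  rowSums(obs[, 4:6, drop = FALSE]),
                  rowSums(obs[, 7:9, drop = FALSE]))
  obs_mean <- colMeans(obs)
  obs_cov <- stats::cov(obs)

  set.seed(seed)
  T1_obs <- T1_rep <- T2_obs <- T2_rep <- numeric(n_draws)
  for (d in seq_len(n_draws)) {
    theta <- draws$indiv[d, , , drop = TRUE]
    if (is.null(dim(theta))) theta <- matrix(theta, nrow = n)
    probs <- vec_category_probs(theta)
    expf <- probs * tree_n[, c(1, 1, 1, 2, 2, 2, 3, 3, 3)]
    # model-implied across-participant covariance of category frequencies
    within <- matrix(0, 9L, 9L)
    for (t in 1:3) {
      idx <- (t - 1L) * 3L + 1:3
      pt <- probs[, idx, drop = FALSE]
      Nt <- tree_n[, t]
      for (a in 1:3) for (b in 1:3) {
        within[idx[a], idx[b]] <- within[idx[a], idx[b]] +
          mean(Nt * (ifelse(a == b, pt[, a], 0) - pt[, a] * pt[, b]))
      }
    }
    exp_cov <- stats::cov(expf) + within
    # replicate cohort from the same individual parameters
    rep9 <- matrix(0, n, 9L)
    for (t in 1:3) {
      idx <- (t - 1L) * 3L + 1:3
      for (i in seq_len(n)) {
        rep9[i, idx] <- stats::rmultinom(1L, tree_n[i, t], probs[i, idx])
      }
    }
    exp_mean <- colMeans(expf)
    T1_obs[d] <- sum((obs_mean - exp_mean)^2)
    T1_rep[d] <- sum((colMeans(rep9) - exp_mean)^2)
    T2_obs[d] <- sum((obs_cov - exp_cov)^2)
    T2_rep[d] <- sum((stats::cov(rep9) - exp_cov)^2)
  }
  list(p_T1 = mean(T1_rep >= T1_obs), p_T2 = mean(T2_rep >= T2_obs),
       T1_obs = T1_obs, T1_rep = T1_rep, T2_obs = T2_obs, T2_rep = T2_rep)
}

#' Posterior group differences (young minus older)
#'
#' Subtracts the older group's probability-scale group-mean draws from the
#' young group's, parameter by parameter, pairing draws by index after a
#' seeded random shuffle (the posteriors are independent, so the pairing is
#' arbitrary). Reports the posterior mean difference, the central 95%
#' credible interval, and whether the interval excludes zero.
#'
#' @param draws_young,draws_older `posterior_draws` from independent fits.
#' @param seed seed for the draw alignment (and subsampling when the two
#'   fits have different draw counts).
#' @return A `data.frame`: parameter, mean, lower, upper, excludes_zero.
#' @export
group_difference <- function(draws_young, draws_older, seed = 1L) {
  a <- draws_young$group_mean
  b <- draws_older$group_mean
  set.seed(seed)
  n <- min(nrow(a), nrow(b))
  ia <- sample(nrow(a), n)
  ib <- sample(nrow(b), n)
  diff <- a[ia, , drop = FALSE] - b[ib, , drop = FALSE]
  q <- apply(diff, 2L, stats::quantile, c(0.025, 0.975))
  data.frame(parameter = .PARAM_NAMES,
             mean = colMeans(diff),
             lower = q[1L, ], upper = q[2L, ],
             excludes_zero = q[1L, ] > 0 | q[2L, ] < 0,
             row.names = NULL)
}
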