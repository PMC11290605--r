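# The dual-process source-item multinomial processing tree.
#
# Six parameters, all probabilities:
#   S_up, S_down  recollection: item AND vertical position retrieved jointly
#   I_up, I_down  familiarity: the item is recognized when recollection fails
#   o             guessing "old" when neither recollection nor familiarity
#   g             guessing "up" when a source must be chosen without memory
#
# g governs the source guess both after familiarity succeeds (the position is
# unknown even though the item is recognized) and after an uninformed "old"
# guess; one shared g is the conventional, identifiable choice for this
# topology. The model is just-identified: 6 free category probabilities
# (3 trees x (3 - 1)), 6 parameters.

#' Construct a parameter vector for the source-item MPT
#'
#' @param S_up,S_down probability of recollection (item + position) for items
#'   shown in the upper / lower visual field.
#' @param I_up,I_down probability of familiarity-based item recognition when
#'   recollection fails.
#' @param o probability of guessing "old" without any memory signal.
#' @param g probability of guessing "up" when the source must be guessed.
#' @return A named numeric vector of class `mpt_params`.
#' @export
mpt_params <- function(S_up, S_down, I_up, I_down, o, g) {
  p <- c(S_up = S_up, S_down = S_down, I_up = I_up, I_down = I_down,
         o = o, g = g)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("all MPT parameters must be probabilities in [0, 1]")
  }
  structure(p, class = "mpt_params")
}

as_mpt_params <- function(p) {
  if (inherits(p, "mpt_params")) return(p)
  if (is.null(names(p))) names(p) <- .PARAM_NAMES
  do.call(mpt_params, as.list(p[.PARAM_NAMES]))
}

#' Category probabilities of the source-item MPT
#'
#' Maps the six parameters to the 3x3 matrix of response-category
#' probabilities, one row (summing to 1) per trial tree:
#' \describe{
#'   \item{UP}{`P(old_up) = S_up + (1-S_up) I_up g + (1-S_up)(1-I_up) o g`;
#'     `P(old_down) = (1-S_up) I_up (1-g) + (1-S_up)(1-I_up) o (1-g)`;
#'     `P(new) = (1-S_up)(1-I_up)(1-o)`.}
#'   \item{DOWN}{mirror image with `S_down`, `I_down`; recollection leads to
#'     `old_down`, and `g` is still the probability of guessing "up".}
#'   \item{NEW}{`P(old_up) = o g`; `P(old_down) = o (1-g)`; `P(new) = 1-o`.}
#' }
#'
#' @param params an [mpt_params()] vector.
#' @return 3x3 matrix with rows `UP`, `DOWN`, `NEW` and columns `old_up`,
#'   `old_down`, `new`; each row sums to 1.
#' @export
category_probabilities <- function(params) {
  p <- as_mpt_params(params)
  S_up <- p[["S_up"]]; S_down <- p[["S_down"]]
  I_up <- p[["I_up"]]; I_down <- p[["I_down"]]
  o <- p[["o"]]; g <- p[["g"]]
  up <- c(
    S_up + (1 - S_up) * I_up * g + (1 - S_up) * (1 - I_up) * o * g,
    (1 - S_up) * I_up * (1 - g) + (1 - S_up) * (1 - I_up) * o * (1 - g),
    (1 - S_up) * (1 - I_up) * (1 - o)
  )
  down <- c(
    (1 - S_down) * I_down * g + (1 - S_down) * (1 - I_down) * o * g,
    S_down + (1 - S_down) * I_down * (1 - g) +
      (1 - S_down) * (1 - I_down) * o * (1 - g),
    (1 - S_down) * (1 - I_down) * (1 - o)
  )
  new <- c(o * g, o * (1 - g), 1 - o)
  matrix(c(up, down, new), nrow = 3L, byrow = TRUE,
         dimnames = list(.TREES, .CATEGORIES))
}

#' Multinomial log-likelihood of a frequency table under the MPT
#'
#' Sum over the three trees of `count * log(prob)` (up to the multinomial
#' coefficient, which does not depend on the parameters). Returns `-Inf`
#' when a zero-probability category has a positive count.
#'
#' @param freq a [freq_table()].
#' @param params an [mpt_params()] vector.
#' @return The log-likelihood kernel.
#' @export
mpt_loglik <- function(freq, params) {
  stopifnot(inherits(freq, "freq_table"))
  probs <- category_probabilities(params)
  cts <- freq$counts
  pos <- cts > 0
  if (any(pos & probs == 0)) return(-Inf)
  sum(cts[pos] * log(probs[pos]))
}

#' Closed-form moment estimator for the source-item MPT
#'
#' The model is just-identified, so the observed category proportions invert
#' algebraically: the NEW tree gives `o = 1 - P(new|NEW)` and
#' `g = old_up / (old_up + old_down)`; within each old tree, with
#' `A = P(new|tree)/(1-o) = (1-S)(1-I)` and `B = (1-S) I` recovered from the
#' off-position category, `S = 1 - (A + B)` and `I = B / (A + B)`.
#' Estimates are clipped to `[0, 1]`; sampling noise can push the raw
#' inversion outside the unit interval, in which case `clipped` is `TRUE`.
#'
#' @param freq a [freq_table()].
#' @return A list with `params` ([mpt_params()]), `clipped` (logical), and
#'   `raw` (the unclipped estimates).
#' @export
moment_estimator <- function(freq) {
  stopifnot(inherits(freq, "freq_table"))
  cts <- freq$counts
  n_new <- sum(cts["NEW", ])
  if (n_new == 0) stop("moment estimator undefined: no NEW-tree trials")
  o <- 1 - cts["NEW", "new"] / n_new
  denom_g <- cts["NEW", "old_up"] + cts["NEW", "old_down"]
  if (denom_g == 0) stop("moment estimator undefined: no old responses in the NEW tree (cell NEW/old_up + NEW/old_down is zero)")
  g <- cts["NEW", "old_up"] / denom_g
  if (o >= 1) stop("moment estimator undefined: P(new|NEW) is zero (cell NEW/new)")
  if (g <= 0 || g >= 1) stop("moment estimator undefined: degenerate source guessing (g = ", g, ")")

  solve_tree <- function(tree, off_category) {
    n <- sum(cts[tree, ])
    if (n == 0) stop("moment estimator undefined: no trials in tree ", tree)
    A <- (cts[tree, "new"] / n) / (1 - o)
    g_off <- if (off_category == "old_down") (1 - g) else g
    B <- (cts[tree, off_category] / n) / g_off - A * o
    c(S = 1 - (A + B), I = if (A + B > 0) B / (A + B) else NA_real_)
  }
  up <- solve_tree("UP", "old_down")
  dn <- solve_tree("DOWN", "old_up")
  raw <- c(S_up = up[["S"]], S_down = dn[["S"]], I_up = up[["I"]],
           I_down = dn[["I"]], o = o, g = g)
  clipped_vals <- pmin(1, pmax(0, raw))
  clipped_vals[is.na(clipped_vals)] <- 0
  list(params = as_mpt_params(clipped_vals),
       clipped = any(is.na(raw)) || any(abs(clipped_vals - raw) > 0, na.rm = TRUE),
       raw = raw)
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Maximum-likelihood fit of the source-item MPT
#'
#' Maximizes [mpt_loglik()] over the six probabilities via L-BFGS-B on the
#' logit scale (probabilities clipped away from 0/1 by `eps` to keep the
#' likelihood finite), with seeded multi-start. The model is just-identified,
#' so on interior optima the MLE agrees with [moment_estimator()] to
#' numerical tolerance.
#'
#' Ties across starts break by highest log-likelihood, then lowest parameter
#' L2 norm.
#'
#' @param freq a [freq_table()].
#' @param init optional starting [mpt_params()]; added to the random starts.
#' @param n_starts random multi-starts (default 10).
#' @param seed RNG seed for the starts.
#' @param eps boundary clip on the probability scale (default 1e-9).
#' @return A list with `params`, `loglik`, `g_squared`, `boundary` (logical
#'   per parameter: estimate at the clip boundary), `n_starts`, `seed`,
#'   `convergence` (per-start optim codes).
#' @export
fit_mle <- function(freq, init = NULL, n_starts = 10L, seed = 1L, eps = 1e-9) {
  stopifnot(inherits(freq, "freq_table"))
  neg_ll <- function(x) {
    p <- inv_logit(x)
    -mpt_loglik(freq, pmin(1 - eps, pmax(eps, p)))
  }
  starts <- list()
  # the moment estimator, when defined, is an excellent start
  me <- tryCatch(moment_estimator(freq)$params, error = function(e) NULL)
  if (!is.null(me)) starts <- c(starts, list(pmin(1 - 1e-4, pmax(1e-4, unclass(me)))))
  if (!is.null(init)) starts <- c(starts, list(unclass(as_mpt_params(init))))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  rand <- replicate(n_starts, stats::runif(6L, 0.05, 0.95), simplify = FALSE)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  starts <- c(starts, rand)

  best <- NULL
  codes <- integer(0)
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(logit(pmin(1 - 1e-6, pmax(1e-6, s))), neg_ll,
                   method = "L-BFGS-B", lower = -25, upper = 25,
                   control = list(maxit = 500L, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(fit)) next
    codes <- c(codes, fit$convergence)
    cand <- list(value = fit$value, par = inv_logit(fit$par))
    if (is.null(best) ||
        cand$value < best$value - 1e-10 ||
        (abs(cand$value - best$value) <= 1e-10 &&
         sum(cand$par^2) < sum(best$par^2))) {
      best <- cand
    }
  }
  if (is.null(best)) stop("MLE failed to converge from any start")
  # polish: near a just-identified optimum the likelihood is so flat that
  # multi-start ties can sit ~1e-6 away in parameters; one tight refit from
  # the winner removes that slack
  polish <- tryCatch(
    stats::optim(logit(pmin(1 - 1e-9, pmax(1e-9, best$par))), neg_ll,
                 method = "L-BFGS-B", lower = -25, upper = 25,
                 control = list(maxit = 1000L, factr = 10, pgtol = 1e-12)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value <= best$value) {
    best <- list(value = polish$value, par = inv_logit(polish$par))
  }
  params <- as_mpt_params(pmin(1 - eps, pmax(eps, best$par)))
  list(params = params,
       loglik = -best$value,
       g_squared = g_squared(freq, params),
       boundary = unclass(params) <= eps * 2 | unclass(params) >= 1 - eps * 2,
       n_starts = length(starts),
       seed = seed,
       convergence = codes)
}

#' Likelihood-ratio goodness of fit (G-squared)
#'
#' `2 * sum(observed * log(observed / expected))` with the convention
#' `0 * log(0) = 0`; expected counts come from [category_probabilities()]
#' scaled to each tree's total. At the MLE of this just-identified model the
#' statistic is ~0 for any non-degenerate table.
#'
#' @param freq a [freq_table()].
#' @param params an [mpt_params()] vector.
#' @return The G-squared statistic.
#' @export
g_squared <- function(freq, params) {
  stopifnot(inherits(freq, "freq_table"))
  probs <- category_probabilities(params)
  cts <- freq$counts
  expected <- probs * rowSums(cts)
  pos <- cts > 0
  if (any(pos & expected == 0)) return(Inf)
  2 * sum(cts[pos] * log(cts[pos] / expected[pos]))
}
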