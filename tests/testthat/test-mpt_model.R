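test_that("category probabilities implement the source-item tree", {
  # no memory, no old-guessing: every tree answers "new" with certainty
  p0 <- mpt_params(0, 0, 0, 0, 0, 0.5)
  probs0 <- category_probabilities(p0)
  expect_equal(unname(probs0[, "new"]), c(1, 1, 1))

  # certain recollection forces the correct source answer
  p1 <- mpt_params(1, 0.2, 0.3, 0.4, 0.5, 0.6)
  expect_equal(category_probabilities(p1)["UP", "old_up"], 1)
  p2 <- mpt_params(0.2, 1, 0.3, 0.4, 0.5, 0.6)
  expect_equal(category_probabilities(p2)["DOWN", "old_down"], 1)

  # hand-enumerated branch products for the UP tree
  p <- mpt_params(S_up = 0.5, S_down = 0.5, I_up = 0.4, I_down = 0.4,
                  o = 0.2, g = 0.6)
  expect_equal(unname(category_probabilities(p)["UP", ]),
               c(0.656, 0.104, 0.240))
  # NEW tree is pure guessing
  expect_equal(unname(category_probabilities(p)["NEW", ]),
               c(0.2 * 0.6, 0.2 * 0.4, 0.8))
})

test_that("rows are stochastic and P(new) decreases in o", {
  set.seed(11)
  for (k in 1:200) {
    th <- runif(6)
    probs <- category_probabilities(as_params <- mpt_params(
      th[1], th[2], th[3], th[4], th[5], th[6]))
    expect_equal(unname(rowSums(probs)), c(1, 1, 1), tolerance = 1e-12)
    expect_true(all(probs >= 0 & probs <= 1))
    # monotonicity in o, holding the rest fixed
    if (th[5] < 0.9 && th[1] < 1 && th[2] < 1 && th[3] < 1 && th[4] < 1) {
      up <- mpt_params(th[1], th[2], th[3], th[4], min(1, th[5] + 0.05), th[6])
      expect_true(all(category_probabilities(up)[, "new"] < probs[, "new"]))
    }
  }
})

test_that("log-likelihood equals a brute-force multinomial computation", {
  expect_equal(mpt_loglik(ft9(rep(0, 9)), mpt_params(.1, .2, .3, .4, .5, .6)), 0)
  # a certain branch contributes log(1) = 0
  p1 <- mpt_params(1, 0.5, 0.5, 0.5, 0.5, 0.5)
  expect_equal(mpt_loglik(ft9(c(1, 0, 0, rep(0, 6))), p1), 0)

  set.seed(5)
  for (k in 1:25) {
    params <- mpt_params(runif(1), runif(1), runif(1), runif(1),
                         runif(1), runif(1))
    counts <- matrix(rpois(9, 20), 3)
    ft <- freq_table(counts)
    probs <- category_probabilities(params)
    oracle <- sum(sapply(1:3, function(t) {
      stats::dmultinom(ft$counts[t, ], prob = probs[t, ], log = TRUE) -
        lgamma(sum(ft$counts[t, ]) + 1) + sum(lgamma(ft$counts[t, ] + 1))
    }))
    expect_equal(mpt_loglik(ft, params), oracle, tolerance = 1e-10)
  }
})

test_that("moment estimator inverts the tree algebraically", {
  # NEW tree alone pins o and g
  ft <- ft9(c(60, 20, 20, 20, 60, 20, 12, 8, 80))
  me <- moment_estimator(ft)
  expect_equal(me$params[["o"]], 0.2)
  expect_equal(me$params[["g"]], 0.6)

  # UP tree at the hand-derived probabilities recovers S_up, I_up exactly
  ft2 <- ft9(c(656, 104, 240, 104, 656, 240, 120, 80, 800))
  me2 <- moment_estimator(ft2)
  expect_equal(me2$params[["S_up"]], 0.5, tolerance = 1e-12)
  expect_equal(me2$params[["I_up"]], 0.4, tolerance = 1e-12)
  expect_false(me2$clipped)

  # round trip: probabilities -> scaled counts -> estimator is the identity
  set.seed(8)
  for (k in 1:30) {
    truth <- mpt_params(runif(1, .2, .8), runif(1, .2, .8), runif(1, .2, .8),
                        runif(1, .2, .8), runif(1, .1, .6), runif(1, .2, .8))
    N <- 1e6
    ft3 <- freq_table(round(category_probabilities(truth) * N))
    est <- moment_estimator(ft3)$params
    expect_equal(unclass(est), unclass(truth), tolerance = 1e-4)
  }

  expect_error(moment_estimator(ft9(c(1, 1, 1, 1, 1, 1, 0, 0, 10))),
               "NEW tree")
})

test_that("MLE agrees with the moment estimator on non-degenerate tables", {
  ft <- ft9(c(656, 104, 240, 104, 656, 240, 200, 120, 680))
  me <- moment_estimator(ft)$params
  fit <- fit_mle(ft, seed = 3)
  expect_equal(unclass(fit$params), unclass(me), tolerance = 1e-6)
  expect_lt(fit$g_squared, 1e-6)

  # noiseless counts at known parameters are recovered
  truth <- mpt_params(0.6, 0.55, 0.45, 0.5, 0.25, 0.55)
  ftn <- freq_table(round(category_probabilities(truth) * 1e6))
  fit2 <- fit_mle(ftn, seed = 3)
  expect_equal(unclass(fit2$params), unclass(truth), tolerance = 1e-4)

  # all-"new" data drives the old-guessing rate to the boundary
  fit3 <- fit_mle(ft9(c(0, 0, 80, 0, 0, 80, 0, 0, 80)), seed = 3)
  expect_lt(fit3$params[["o"]], 1e-6)
  expect_true(fit3$boundary[["o"]])
})

test_that("G-squared is zero at a saturated fit and matches direct recomputation", {
  params <- mpt_params(0.5, 0.5, 0.4, 0.4, 0.2, 0.6)
  ft <- freq_table(round(category_probabilities(params) * 1000))
  expect_equal(g_squared(ft, params), 0, tolerance = 1e-10)

  perturbed <- mpt_params(0.45, 0.5, 0.4, 0.4, 0.25, 0.6)
  expected <- category_probabilities(perturbed) * rowSums(ft$counts)
  oracle <- 2 * sum(ifelse(ft$counts > 0,
                           ft$counts * log(ft$counts / expected), 0))
  expect_equal(g_squared(ft, perturbed), oracle)
  expect_gt(g_squared(ft, perturbed), 0)
})
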