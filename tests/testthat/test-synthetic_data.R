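test_that("generation is fully deterministic under a fixed seed", {
  spec <- cohort_spec(n_young = 3L, n_older = 2L, trials_per_tree = 24L,
                      seed = 5L)
  s1 <- gen_cohort(spec)
  s2 <- gen_cohort(spec)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$truth$params, s2$truth$params)

  expect_identical(gen_gaze("stable", 3, seed = 8),
                   gen_gaze("stable", 3, seed = 8))
  c1 <- gen_isopters(25, seed = 4)
  c2 <- gen_isopters(25, seed = 4)
  expect_identical(c1$radius_deg, c2$radius_deg)
})

test_that("with no latent variation and no misses, frequencies approach the model", {
  spec <- cohort_spec(n_young = 1L, n_older = 1L, trials_per_tree = 1e5L,
                      latent_sd = 0, miss_rate = 0, n_blocks = 8L, seed = 2L)
  sim <- gen_cohort(spec)
  cohort <- cohort_table(sim$trials)
  for (g in c("young", "older")) {
    id <- names(cohort$group)[cohort$group == g]
    emp <- cohort$tables[[id]]$counts / 1e5
    expect_equal(unclass(emp),
                 unclass(category_probabilities(spec$group_means[[g]])),
                 tolerance = 0.01, ignore_attr = TRUE)
    expect_equal(unname(sim$truth$params[id, ]),
                 unname(unclass(spec$group_means[[g]])))
  }
})

test_that("empirical parameter means converge to the group means over participants", {
  spec <- cohort_spec(n_young = 400L, n_older = 1L, trials_per_tree = 3L,
                      latent_sd = 0.3, seed = 14L)
  sim <- gen_cohort(spec)
  young_mean <- colMeans(sim$truth$params[sim$truth$group == "young", ])
  # probit-normal means are pulled slightly toward 0.5; allow for both the
  # transform bias (~ <= 0.015 at these values) and 1/sqrt(400) noise
  expect_equal(unname(young_mean), unname(unclass(spec$group_means$young)),
               tolerance = 0.04)
})

test_that("trials spread evenly over blocks and the miss process is group-specific", {
  spec <- cohort_spec(n_young = 1L, n_older = 1L, trials_per_tree = 80L,
                      miss_rate = c(young = 0, older = 1), seed = 6L)
  sim <- gen_cohort(spec)
  young <- sim$trials[sim$trials$group == "young", ]
  expect_equal(unname(table(young$block)), rep(30L, 8L), ignore_attr = TRUE)
  expect_false(any(young$item_response == "miss"))
  older <- sim$trials[sim$trials$group == "older", ]
  expect_true(all(older$item_response == "miss"))
})

test_that("generated gaze classifies into the requested Fujii category", {
  for (s in c("stable", "relatively_unstable", "unstable")) {
    for (sd in c(1L, 9L)) {
      g <- gen_gaze(s, 5, seed = sd)
      r <- fujii_classify(detect_fixations(g))
      expect_equal(r$category, s)
      expect_equal(r$excluded, s == "unstable")
    }
  }
  # degenerate single still epoch: one fixation at the center
  g0 <- gen_gaze("stable", 1, seed = 1, jitter = 0, n_epochs = 1L)
  fx <- detect_fixations(g0)
  expect_equal(nrow(fx), 1L)
  expect_equal(c(fx$cx, fx$cy), c(0, 0))
})

test_that("generated isopters hit the target VMA and mirror under sign flip", {
  ch0 <- gen_isopters(0, seed = 3)
  a0 <- hemifield_areas(ch0)
  expect_equal(vma_index(a0$upper_area, a0$lower_area)$vma, 0,
               tolerance = 0.01)

  ch40 <- gen_isopters(40, seed = 3)
  a40 <- hemifield_areas(ch40)
  v40 <- vma_index(a40$upper_area, a40$lower_area)$vma
  expect_true(v40 >= 39 && v40 <= 41)

  chm40 <- gen_isopters(-40, seed = 3)
  am40 <- hemifield_areas(chm40)
  vm40 <- vma_index(am40$upper_area, am40$lower_area)$vma
  expect_equal(vm40, -v40, tolerance = 0.01)

  expect_error(gen_isopters(250), "infeasible")
})

test_that("cohort specifications validate their inputs", {
  expect_error(cohort_spec(n_young = 0L), "at least one participant")
  bad_corr <- matrix(0.99, 6, 6); diag(bad_corr) <- 1; bad_corr[1, 2] <- -0.99
  expect_error(cohort_spec(latent_corr = bad_corr), "positive-definite")
})

test_that("ground truth serializes to a JSON sidecar with seed and parameters", {
  sim <- gen_cohort(cohort_spec(n_young = 2L, n_older = 1L,
                                trials_per_tree = 12L, seed = 8L))
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(sim$truth, path)
  gt <- jsonlite::read_json(path)
  expect_equal(gt$seed, 8L)
  expect_equal(length(gt$participants), 3L)
  expect_equal(gt$participants[[1L]]$params$S_up,
               unname(sim$truth$params[1L, "S_up"]))
})
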