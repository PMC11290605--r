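test_that("item Pr is hits minus false alarms and reproduces group-level values", {
  # rates at the young/older group means
  expect_equal(item_pr(0.815, 0.044), 0.771)
  expect_equal(round(item_pr(0.815, 0.044), 2), 0.77)
  expect_equal(item_pr(0.691, 0.102), 0.589)
  expect_equal(round(item_pr(0.691, 0.102), 2), 0.59)
  # symmetry and antisymmetry
  for (x in c(0, 0.3, 1)) expect_equal(item_pr(x, x), 0)
  expect_equal(item_pr(0.8, 0.1), -item_pr(0.1, 0.8))
  expect_error(item_pr(1.2, 0), "proportions")
})

test_that("source Pr normalizes by the fixed source-trial total", {
  expect_equal(source_trials_total(), 160L)
  expect_equal(source_pr(160, 0), 1)
  expect_equal(source_pr(80, 80), 0)
  expect_equal(source_pr(100, 40), 0.375)
  expect_error(source_pr(-1, 0), "non-negative")
  expect_error(source_pr(100, 80), "exceeds")
  # bounded and monotone
  set.seed(1)
  for (k in 1:20) {
    a <- sample(0:160, 1); b <- sample(0:(160 - a), 1)
    v <- source_pr(a, b)
    expect_true(v >= -1 && v <= 1)
    if (a + b < 160) {
      expect_gt(source_pr(a + 1, b), v)
      expect_lt(source_pr(a, b + 1), v)
    }
  }
  # alternative designs change the denominator
  expect_equal(source_pr(10, 0, total = source_trials_total(2, 10)), 0.5)
})

test_that("group summary matches direct recomputation from raw trials", {
  spec <- cohort_spec(n_young = 4L, n_older = 3L, trials_per_tree = 40L,
                      miss_rate = 0.05, seed = 31L)
  sim <- gen_cohort(spec)
  cohort <- cohort_table(sim$trials)
  gs <- group_summary(cohort, trials_per_tree = 40L)

  # independent recomputation straight from trial rows
  direct <- function(g) {
    ids <- unique(sim$trials$participant_id[sim$trials$group == g])
    rates <- t(vapply(ids, function(id) {
      tr <- sim$trials[sim$trials$participant_id == id, ]
      old <- tr$true_position != "new"
      c(hit = mean(tr$item_response[old] == "old"),
        fa = mean(tr$item_response[!old] == "old"))
    }, numeric(2)))
    c(hit = mean(rates[, 1]), fa = mean(rates[, 2]),
      hit_sd = sd(rates[, 1]))
  }
  for (g in c("young", "older")) {
    d <- direct(g)
    row <- gs[gs$group == g, ]
    expect_equal(row$hit_mean, unname(d["hit"]))
    expect_equal(row$fa_mean, unname(d["fa"]))
    expect_equal(row$hit_sd, unname(d["hit_sd"]))
    # linearity: mean item Pr = mean hit - mean FA
    expect_equal(row$item_pr_mean, row$hit_mean - row$fa_mean)
  }
})

test_that("a perfect no-miss participant scores hit 1, FA 0, CR 1; identical participants give SD 0", {
  perfect <- freq_table(matrix(c(80, 0, 0, 0, 80, 0, 0, 0, 80), 3, byrow = TRUE))
  st <- pr_stats(perfect)
  expect_equal(st$hit_rate, 1)
  expect_equal(st$fa_rate, 0)
  expect_equal(st$cr_rate, 1)
  expect_equal(st$item_pr, 1)
  expect_equal(st$source_pr, 1)

  # misses sit in the denominator: they depress the rate, not the count base
  missed <- freq_table(matrix(c(70, 0, 0, 0, 70, 0, 0, 0, 75), 3, byrow = TRUE),
                       n_miss = 25L)
  st2 <- pr_stats(missed)
  expect_equal(st2$hit_rate, 140 / 160)
  expect_equal(st2$cr_rate, 75 / 80)

  trials <- rbind(tiny_trials("p1"), tiny_trials("p2"))
  gs <- group_summary(cohort_table(trials), trials_per_tree = 2L)
  expect_equal(gs$hit_sd, 0)
  expect_equal(gs$item_pr_sd, 0)
})

test_that("false-alarm VMA follows the perimetry formula and flags 0/0", {
  expect_equal(false_alarm_vma(5, 5)$vma, 0)
  expect_equal(false_alarm_vma(0, 10)$vma, 200)
  expect_equal(false_alarm_vma(4, 6)$vma, 40)
  und <- false_alarm_vma(0, 0)
  expect_false(und$defined)
  expect_true(is.na(und$vma))
  expect_error(false_alarm_vma(-1, 2), "non-negative")
})
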