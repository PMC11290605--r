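# Discrimination (Pr) statistics for the source-monitoring task.
#
# Item Pr is the Snodgrass & Corwin discrimination index: hit rate minus
# false-alarm rate. Source Pr normalizes correct-minus-incorrect source
# judgments by the number of source trials a perfect item-memory performer
# would face, so participants who answer "new" often are not advantaged.

# Source trials under the standard design: 8 blocks x 20 re-presented
# objects per block. Overridable for other designs.
#' Number of source trials under the standard design
#'
#' 8 blocks times 20 re-presented (old) objects per test phase = 160; this is
#' the fixed denominator of the source Pr so that discrimination is comparable
#' across participants with different numbers of answered source prompts.
#'
#' @param n_blocks number of blocks (default 8).
#' @param old_per_block re-presented old objects per test phase (default 20).
#' @return Integer count of source trials for a perfect item-memory score.
#' @export
source_trials_total <- function(n_blocks = 8L, old_per_block = 20L) {
  as.integer(n_blocks) * as.integer(old_per_block)
}

#' Item discrimination index (Pr)
#'
#' `Pr = hit_rate - fa_rate`: the proportion of old items correctly called
#' "old" minus the proportion of new items incorrectly called "old".
#'
#' @param hit_rate proportion of hits in `[0, 1]`.
#' @param fa_rate proportion of false alarms in `[0, 1]`.
#' @return `hit_rate - fa_rate`, in `[-1, 1]`.
#' @export
item_pr <- function(hit_rate, fa_rate) {
  if (any(hit_rate < 0 | hit_rate > 1) || any(fa_rate < 0 | fa_rate > 1)) {
    stop("hit_rate and fa_rate must be proportions in [0, 1]")
  }
  hit_rate - fa_rate
}

#' Source discrimination index (Pr)
#'
#' `(correct - incorrect) / total`, with `total` fixed at the number of
#' source trials a participant with perfect item memory would see
#' ([source_trials_total()], 160 in the standard design).
#'
#' @param correct number of correct up/down source judgments.
#' @param incorrect number of incorrect source judgments.
#' @param total fixed denominator (default [source_trials_total()]).
#' @return Source Pr in `[-1, 1]`.
#' @export
source_pr <- function(correct, incorrect, total = source_trials_total()) {
  if (any(correct < 0) || any(incorrect < 0)) {
    stop("source judgment counts must be non-negative")
  }
  if (any(correct + incorrect > total)) {
    stop("correct + incorrect exceeds the number of source trials (", total, ")")
  }
  (correct - incorrect) / total
}

#' Per-participant accuracy rates from a frequency table
#'
#' Rates use all presented trials of the relevant type as denominator, so
#' missed trials count in the denominator but never the numerator (which is
#' why group hit/FA/CR rates need not sum to 100% with their complements).
#' Misses are apportioned to trees proportionally to presented trials when
#' only the aggregate `n_miss` is known; with the standard balanced design
#' the three trees have equal trial counts.
#'
#' @param ft a [freq_table()].
#' @param trials_per_tree presented trials per tree (default 80).
#' @return A one-row `data.frame` with hit, FA, CR rates, item and source Pr,
#'   and the source-judgment counts.
#' @export
pr_stats <- function(ft, trials_per_tree = 80L) {
  stopifnot(inherits(ft, "freq_table"))
  cts <- ft$counts
  n_old_presented <- 2L * trials_per_tree       # UP + DOWN trees
  n_new_presented <- trials_per_tree
  hits <- cts["UP", "old_up"] + cts["UP", "old_down"] +
    cts["DOWN", "old_up"] + cts["DOWN", "old_down"]
  fas <- cts["NEW", "old_up"] + cts["NEW", "old_down"]
  crs <- cts["NEW", "new"]
  source_correct <- cts["UP", "old_up"] + cts["DOWN", "old_down"]
  source_incorrect <- cts["UP", "old_down"] + cts["DOWN", "old_up"]
  data.frame(
    hit_rate = hits / n_old_presented,
    fa_rate = fas / n_new_presented,
    cr_rate = crs / n_new_presented,
    item_pr = hits / n_old_presented - fas / n_new_presented,
    source_correct = source_correct,
    source_incorrect = source_incorrect,
    source_pr = source_pr(source_correct, source_incorrect,
                          total = 2L * trials_per_tree)
  )
}

#' Group summary of accuracy rates and Pr statistics
#'
#' Mean and SD over participants, per group, of hit/FA/CR rates and the item
#' and source Pr — the content of a standard accuracy summary table.
#'
#' @param cohort a [cohort_table()].
#' @param trials_per_tree presented trials per tree (default 80).
#' @return A `data.frame` with one row per group: n, then `<stat>_mean` and
#'   `<stat>_sd` for hit, fa, cr, item_pr, source_pr.
#' @export
group_summary <- function(cohort, trials_per_tree = 80L) {
  stopifnot(inherits(cohort, "cohort_table"))
  per <- do.call(rbind, lapply(cohort$tables, pr_stats,
                               trials_per_tree = trials_per_tree))
  per$group <- cohort$group
  groups <- intersect(.GROUPS, unique(per$group))
  rows <- lapply(groups, function(g) {
    sub <- per[per$group == g, , drop = FALSE]
    if (nrow(sub) == 0L) stop("empty group: ", g)
    data.frame(
      group = g, n = nrow(sub),
      hit_mean = mean(sub$hit_rate), hit_sd = stats::sd(sub$hit_rate),
      fa_mean = mean(sub$fa_rate), fa_sd = stats::sd(sub$fa_rate),
      cr_mean = mean(sub$cr_rate), cr_sd = stats::sd(sub$cr_rate),
      item_pr_mean = mean(sub$item_pr), item_pr_sd = stats::sd(sub$item_pr),
      source_pr_mean = mean(sub$source_pr), source_pr_sd = stats::sd(sub$source_pr)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Vertical asymmetry of false-alarm source attributions
#'
#' Applies the perimetry-style vertical meridian asymmetry formula to the
#' counts of "down" versus "up" source attributions for false alarms:
#' `(down - up) / mean(down, up) * 100`. Positive values indicate a bias
#' toward attributing never-seen items to the lower visual field. Undefined
#' when both counts are zero (returned as `NA` with a flag rather than NaN).
#'
#' @param fa_up false alarms attributed to the upper field.
#' @param fa_down false alarms attributed to the lower field.
#' @return A list with `vma` (number or `NA`) and `defined` (logical).
#' @export
false_alarm_vma <- function(fa_up, fa_down) {
  if (fa_up < 0 || fa_down < 0) stop("false-alarm counts must be non-negative")
  if (fa_up == 0 && fa_down == 0) {
    return(list(vma = NA_real_, defined = FALSE))
  }
  list(vma = (fa_down - fa_up) / mean(c(fa_down, fa_up)) * 100, defined = TRUE)
}
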