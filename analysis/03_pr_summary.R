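#!/usr/bin/env Rscript
# Standard discrimination statistics: per-group hit / false-alarm / correct-
# rejection rates and the item and source Pr indices, computed on the
# QC-retained participants.
library(vfmemory)

trials <- read_trials("results/data/trials.csv")
qc <- read.csv("results/gaze_qc.csv")
trials <- trials[!trials$participant_id %in% qc$participant_id[qc$excluded], ]

cohort <- cohort_table(trials)
summary <- group_summary(cohort)
write.csv(summary, "results/pr_summary.csv", row.names = FALSE)

cat("Group accuracy summary (mean over participants):\n")
print(summary, digits = 3)
cat(sprintf("Item Pr: young %.2f vs older %.2f; source Pr: young %.2f vs older %.2f\n",
            summary$item_pr_mean[summary$group == "young"],
            summary$item_pr_mean[summary$group == "older"],
            summary$source_pr_mean[summary$group == "young"],
            summary$source_pr_mean[summary$group == "older"]))
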