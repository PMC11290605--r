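#!/usr/bin/env Rscript
# Simulate the full synthetic study: a 25 young + 20 older cohort performing
# the source-monitoring task (8 blocks; 80 up-old, 80 down-old, 80 new test
# trials each), per-participant gaze streams (three participants forced to
# unstable fixation so the QC stage has work to do), and per-participant
# isopter charts whose target VMA is higher in the older group.
library(vfmemory)

seed <- 2026L
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

spec <- cohort_spec(seed = seed)   # study-scale defaults
paths <- run_simulation("results/data", spec, n_unstable = 3L,
                        gaze_duration_s = 5, vma_young = 20, vma_older = 33)

trials <- read_trials(paths$trials)
cat("Simulated", length(unique(trials$participant_id)), "participants,",
    nrow(trials), "test trials (seed", seed, ")\n")
cat("Files:", paste(unlist(paths), collapse = ", "), "\n")
cat("Miss rate observed:",
    round(mean(trials$item_response == "miss"), 4), "\n")
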