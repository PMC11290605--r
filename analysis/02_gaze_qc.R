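#!/usr/bin/env Rscript
# Fixation-stability quality control: detect fixations (velocity threshold,
# 100-ms minimum duration), grade each participant with the Fujii 2/4
# method, and list who is excluded (< 75% of fixation centroids inside 4
# degrees) before any modelling.
library(vfmemory)

gaze <- read_gaze("results/data/gaze.csv")
qc <- gaze_qc_report(gaze)
write.csv(qc, "results/gaze_qc.csv", row.names = FALSE)

cat("Graded", nrow(qc), "participants:",
    sum(qc$category == "stable"), "stable,",
    sum(qc$category == "relatively_unstable"), "relatively unstable,",
    sum(qc$category == "unstable"), "unstable\n")
cat("Excluded:", paste(qc$participant_id[qc$excluded], collapse = ", "), "\n")
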