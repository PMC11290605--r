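#!/usr/bin/env Rscript
# Kinetic-perimetry geometry: hemifield areas along the horizontal meridian
# and the vertical meridian asymmetry index per participant, eye, and
# isopter (I1e parsed but excluded from the analysis set), with group means.
library(vfmemory)

points <- read_isopters("results/data/isopters.csv")
tab <- vma_table(points)
write.csv(tab, "results/vma.csv", row.names = FALSE)

truth <- jsonlite::read_json("results/data/ground_truth.json")
group_of <- vapply(truth$participants, function(p) p$group, character(1))
names(group_of) <- vapply(truth$participants, function(p) p$id, character(1))
tab$group <- group_of[tab$participant_id]

for (g in c("young", "older")) {
  v <- tab$vma[tab$group == g]
  cat(sprintf("%s: mean VMA %.2f (SD %.2f, n = %d charts)\n",
              g, mean(v), sd(v), length(v)))
}
cat("Wrote results/vma.csv\n")
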