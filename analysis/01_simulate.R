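#!/usr/bin/env Rscript
# Generates the synthetic two-group cognitive-skill cohort (122 children:
# 71 controls, 51 with dyslexia, 9 test scores, 5% variance-inflated
# outliers) and its extension with 81 borderline units, and writes both to
# results/ as CSV with truth sidecars.

library(cnmix)

seed <- 20260920
dir.create("results", showWarnings = FALSE)

sim <- dyslexia_preset(seed)
write_dataset(sim$data, "results/cohort.csv", truth = sim$truth)
cat(sprintf("cohort: %d x %d, %d/%d group sizes, %d true bad points\n",
            sim$data$n, sim$data$p,
            sum(sim$truth$labels == 1), sum(sim$truth$labels == 2),
            sum(sim$truth$bad)))

ext <- unclassified_preset(seed)
write_dataset(ext$data, "results/cohort_extended.csv", truth = ext$truth)
cat(sprintf("extended cohort: %d units (%d borderline appended)\n",
            ext$data$n, sum(ext$truth$unclassified)))
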