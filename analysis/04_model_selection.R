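#!/usr/bin/env Rscript
# Secondary analysis: add the 81 borderline units and ask whether the
# information criteria still support two clusters, then assign every
# borderline unit to one of the established groups under the frozen fit.

library(cnmix)

seed <- 20260920
ext <- load_dataset("results/cohort_extended.csv", label_column = "group")
truth <- utils::read.csv("results/cohort_extended_truth.csv")
unclassified <- c(rep(FALSE, 122), rep(TRUE, 81))

cfg <- fit_config(n_init = 4, seed = seed)
tab <- sweep_models(ext, 1:4, c("EII", "VII", "EEI", "VEI", "EVI", "VVI"), cfg)
write_criteria_table(tab, "results/criteria_extended.csv")

bb <- best_by(tab)
for (nm in names(bb))
  cat(sprintf("%-5s -> %s with G = %d\n", nm, bb[[nm]]$model, bb[[nm]]$G))
g_bic <- bb[["BIC"]]$G
cat("clusters supported by BIC:", g_bic, "\n")

# frozen two-cluster model fitted on the diagnosed 122, then applied to the
# borderline units
base <- cnmix_dataset(ext$values[!unclassified, ],
                      variable_names = ext$variable_names)
fit <- fit_ecm(base, 2, "EVI", fit_config(n_init = 10, seed = seed))
appended <- cnmix_dataset(ext$values[unclassified, ],
                          variable_names = ext$variable_names)
pred <- predict(fit, appended)
assign_tab <- table(factor(pred$labels, levels = 1:2))
cat(sprintf("borderline units assigned: %d to cluster 1, %d to cluster 2; %d flagged as outliers\n",
            assign_tab[1], assign_tab[2], sum(pred$bad_flags)))
utils::write.csv(
  data.frame(unit = which(unclassified), label = pred$labels,
             bad = pred$bad_flags),
  "results/unclassified_assignments.csv", row.names = FALSE)
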