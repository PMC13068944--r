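#!/usr/bin/env Rscript

# Stage 1: simulate plate-count tables for three induction/reversal
# conditions spanning the qualitative memory regimes — fast decay of the
# induced excess (low-dose-like), slow decay (high-dose-like), and no
# retention (inducer-free-like). Each condition: 5 induction generations,
# 5 reversal generations, 30 plates x 20 animals per generation.
#
# Writes results/plate_counts.csv.

library(mouthform)

seed <- 20260929L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

conditions <- c(fast_decay = "cond_fast", slow_decay = "cond_slow",
                no_retention = "cond_none")

tables <- lapply(names(conditions), function(nm) {
  scen <- scenario_preset(nm)
  truth <- build_trajectory(scen)
  message(sprintf("%-13s omega trajectory (reversal): %s", nm,
                  paste(sprintf("%.2f",
                                truth$omega_true[truth$phase == "reversal"]),
                        collapse = " ")))
  simulate_counts(truth, scen, seed = seed + match(nm, names(conditions)),
                  condition_id = conditions[[nm]])
})
tab <- do.call(rbind, tables)
write_plate_table(tab, file.path(out_dir, "plate_counts.csv"))
message(sprintf("wrote %s: %d plates over %d condition-generations",
                file.path(out_dir, "plate_counts.csv"), nrow(tab),
                length(unique(paste(tab$condition_id, tab$generation)))))
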