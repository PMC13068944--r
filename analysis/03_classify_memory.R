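#!/usr/bin/env Rscript

# Stage 3: turn per-generation posterior summaries into memory calls. A
# reversal generation is "elevated" when the lower bound of its 95% HDI
# lies strictly above the baseline band (upper bound 0.5 for this
# ~30%-Eu-baseline setting); memory duration is the number of consecutive
# elevated generations from R1; 0 -> none, 1-2 -> intergenerational,
# >= 3 -> transgenerational.
#
# Reads  results/group_summaries.csv.
# Writes results/memory_calls.csv.

library(mouthform)

summaries <- read.csv("results/group_summaries.csv",
                      stringsAsFactors = FALSE)
band <- baseline_band(bounds = c(0.2, 0.5))
calls <- classify_memory(summaries, band)
print(calls, row.names = FALSE)
write.csv(calls, "results/memory_calls.csv", row.names = FALSE,
          quote = FALSE)
message("wrote results/memory_calls.csv")
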