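#!/usr/bin/env Rscript
# Extrapolate per-band cost differences to the national annual excess cost:
# cost difference x exposure prevalence x children in the band, summed, with a
# 1000-resample mother-level bootstrap interval (normal approximation).

library(mmicohort)

ds <- read_dataset("results/data")
costs <- read.csv("results/costs.csv")

nat <- bootstrap_ci(costs, ds$population, n_boot = 1000L, seed = 20170731)
print(nat)

out <- nat$per_band
out$total <- nat$total
out$ci_low <- nat$ci_low
out$ci_high <- nat$ci_high
write.csv(out, "results/national_cost.csv", row.names = FALSE)
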