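#!/usr/bin/env Rscript
# Count healthcare-use events per segment and outcome (same-day same-type
# events counted once), attach inflation-adjusted tariff costs, and tabulate
# prescriptions by drug category.

library(mmicohort)

ds <- read_dataset("results/data")
seg <- read.csv("results/segments_main.csv",
                colClasses = c(band_start_date = "Date", seg_start = "Date",
                               seg_end = "Date"))

counts <- count_events(ds$use_events, seg)
write.csv(counts, "results/counts.csv", row.names = FALSE)
cat("Count records:", nrow(counts),
    "| events outside follow-up dropped:", attr(counts, "n_dropped"), "\n")

costs <- cost_rates(ds$use_events, seg, ds$tariffs, ds$cpi)
write.csv(costs, "results/costs.csv", row.names = FALSE)
crude <- two_group_rates(costs, value_col = "cost")
cat(sprintf("Crude cost rates (GBP/child-year): exposed %.0f, unexposed %.0f\n",
            crude$rate_exposed, crude$rate_unexposed))

drugs <- tabulate_by_drug_category(ds$use_events, seg)
write.csv(drugs, "results/drug_categories.csv", row.names = FALSE)
cat("Prescription rate ratios by drug category:\n")
print(drugs[, c("drug_category", "rate_exposed", "rate_unexposed",
                "rate_ratio")], digits = 3)
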