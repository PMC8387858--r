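#!/usr/bin/env Rscript
# Classify mothers as mental illness cases from their coded events: a
# diagnosis, a prescription within 91 days of a same-illness symptom, or a
# prescription/symptom with a matching historical diagnosis.

library(mmicohort)

ds <- read_dataset("results/data")
det <- classify_cases(ds$clinical_events, ds$codelist)
write.csv(det, "results/determinations.csv", row.names = FALSE)

cat("Determinations:", nrow(det), "for",
    length(unique(det$mother_id)), "case mothers\n")
cat("Unknown codes ignored:", attr(det, "n_unknown_codes"), "\n")
print(table(det$pathway))
cat("By illness:\n")
print(sort(table(det$illness), decreasing = TRUE))
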