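Package: mmicohort
Title: Healthcare Use and Costs of Children Exposed to Maternal Mental Illness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A retrospective-cohort analysis pipeline for quantifying the
    healthcare use and direct NHS costs of children exposed to maternal mental
    illness, driven by mother-child linked primary/secondary care records in
    CPRD GOLD + HES shaped tables. Implements rule-based maternal mental
    illness phenotyping from coded clinical events, eligibility and
    person-time construction across five childhood age bands, healthcare event
    counting with same-day deduplication, tariff-based inflation-adjusted
    costing, negative binomial rate-ratio and rate-difference estimation with
    mother-clustered robust variance, and cluster-bootstrap extrapolation of
    the excess national cost. Includes a synthetic data generator emulating
    the statistical structure the models assume (sibship-clustered
    overdispersed counts, dated exposure onsets, registration churn), so the
    whole pipeline runs and is testable without access-restricted data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    MASS,
    sandwich,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
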