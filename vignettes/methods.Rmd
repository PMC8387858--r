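---
title: "Methods: healthcare use and costs of children exposed to maternal mental illness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: healthcare use and costs of children exposed to maternal mental illness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmicohort)
```

## The question and the design

Children whose mothers live with mental illness are known to be at elevated
risk of mental-health problems, but their *general* healthcare use — GP
contacts, prescriptions, referrals, out-patient visits, admissions, emergency
care — and what it costs a health system, is far less documented.
`mmicohort` implements a retrospective mother-child linked cohort design
over primary-care records (CPRD GOLD shaped) linked to secondary-care
activity (HES shaped): children aged 0-17 observed between 1 April 2007 and
31 July 2017 are classed, per age band, as exposed or unexposed to maternal
mental illness (MMI), their healthcare events are counted and costed, and
exposed-unexposed contrasts are estimated as rate ratios and rate
differences, then extrapolated to an annual national excess cost.

Real CPRD/HES extracts are access-restricted, so the package ships a
synthetic-data generator that reproduces the statistical structure the
estimators rely on; every stage of the pipeline is exercised and tested
against it.

## Phenotyping maternal mental illness

Mothers' coded events (diagnoses, symptoms, prescriptions) are resolved
through a code list covering eight illnesses: non-affective and affective
psychosis, depression, anxiety, eating disorders, personality disorders, and
substance and alcohol misuse. A mother is a case of an illness on a date
through one of three pathways:

1. a **diagnosis**, on its own date;
2. a **prescription within 3 months of a symptom** of the same illness, on
   the later date of the pair;
3. a **prescription or symptom with a matching historical diagnosis**
   (same illness, strictly earlier), on its own date.

Numerical choices the sources of the rules leave open, and how we fixed
them:

* "3 months" is 91 days, counted inclusively. The window is symmetric by
  default — the prescription may precede or follow the symptom — with a
  `symmetric = FALSE` switch for the directional (symptom-then-prescription)
  reading, since the clinical narrative suggests treatment follows
  presentation but coding order in GP records is unreliable.
* "Historical" means any strictly earlier same-illness diagnosis, with
  unbounded look-back within the available record; no horizon is defensible
  without a stated one.
* When one date qualifies through several pathways the most direct label is
  kept (diagnosis, then prescription-near-symptom, then event-with-history);
  the date, which is all downstream code uses, is unaffected.
* Unknown codes are counted and ignored rather than fatal: code lists in the
  wild are always incomplete.

Exposure categories roll illnesses up: **CMI** (depression, anxiety),
**SMI** (the psychoses), **addiction** (substance, alcohol), and **any**
(all eight; eating and personality disorders appear only here). Categories
are deliberately not mutually exclusive.

## Cohort, person-time and exposure windows

Follow-up runs from the latest of birth, practice up-to-standard date,
registration date and the study start, to the earliest of transfer-out, 18th
birthday, child death, mother death, practice data collection end and the
study end. Children are excluded without HES linkage, with under 30.5 days
of follow-up, with a mother not registered at an up-to-standard practice at
follow-up start, or with a mother holding less than 2 years (730 days) of
registration either side of that date. The 30.5-day rule is applied to
computed in-study follow-up, not raw registration length, because the
requirement is about observable person-time.

Follow-up is split at the calendrical 1st, 5th, 10th and 14th birthdays into
five bands (<1, 1-4, 5-9, 10-13, 14-17). All date intervals are half-open
`[start, end)`, person-years use the 365.25-day year, and 29 February
birthdays map to 28 February in non-leap years; these conventions make
person-time conservation exact (tested to 1e-9 years) and keep band
boundaries unambiguous.

A child is exposed for a band when the mother has a case determination
between 730 days before the band start and the end of the child's *observed*
segment in that band. Using the observed segment end rather than the nominal
band end avoids classifying exposure on unobserved time for children
censored mid-band; the nominal-end reading would only add exposure time that
no counted event can fall into. The sensitivity definition closes the window
the day before the band starts (exposure during the band ignored, probing
reverse causation), and is provably a subset of the main definition — a
property the tests assert on every synthetic cohort.

## Counting and costing

Healthcare use spans six outcomes: primary care contacts, prescriptions,
referrals, out-patient visits, in-patient admissions and A&E visits.
Multiple same-type events on one date count once. "Same type" is resolved at
the subtype level — consultation-by-staff pair for primary care, drug code
for prescriptions, outcome level elsewhere — because costing differs by
subtype, and collapsing across subtypes would corrupt costs; a
`dedup_level = "outcome"` switch gives the coarser reading.

Events are costed from annual tariff tables: primary care by consultation
and staff type; prescriptions by drug, falling back to the year's average
unit cost when no drug-specific cost exists; out-patient, A&E and referrals
at annual average unit costs; admissions by episode type, with per-bed-day
costs added for elective and non-elective stays
(`per_admission + per_bed_day x length_of_stay`; a pure bed-day form is
available since the sources underdetermine the functional form). All costs
are CPI-inflated to a 2017 base year; only index *ratios* matter, so any
rescaling of the index leaves costs unchanged (tested). The shipped tariff
and CPI tables are synthetic stand-ins with plausible UK magnitudes — real
analyses substitute the published schedules with the same schema.

## Rate models

For each outcome and exposure category, counts per (child, age band) segment
are modelled by NB2 negative binomial regression (variance
$\mu + \alpha\mu^2$, one estimated dispersion scalar) with log link,
offset $\log(\text{person-years})$, a categorical period covariate (the year
the band started), age band, and an age-band-by-exposure interaction; the
band-specific rate ratio is the exponentiated exposure contrast at that
band. The pooled ("all ages") estimate refits without the interaction.
Standard errors come from the Huber-White sandwich estimator clustered on
the mother, which is what makes siblings' correlated counts (shared gamma
frailty in the generator) honest in the intervals; the tests check both that
cluster-robust SEs exceed iid SEs under planted sibship correlation and that
95% intervals cover a planted total-use ratio of 1.27 at nominal rates
(200 replicate cohorts of 20,000 mothers).

A rate *difference* is not a native quantity of a log-link model; we report
marginal standardization — the person-year-weighted average of model
predictions with exposure switched on versus off over the observed covariate
rows — alongside the crude two-group difference. Interval estimates for
differences use the mother-level bootstrap of the crude differences (the
same clustering unit as everywhere else) rather than a delta method, keeping
the absolute-scale inference assumption-light. In the Poisson limit
(`dispersion = 0`) with no covariates both standardized rates collapse to
the crude arm rates exactly — the closed-form oracle the tests verify to
1e-6.

Degenerate cells (an all-zero arm) report an undefined rate ratio with a
flag rather than an infinite estimate. Non-convergent NB fits restart from
Poisson estimates, then fail loudly.

## National extrapolation

Per band, the excess is (cost difference per exposed child-year) x (MMI
prevalence) x (children in the band nationally), summed over bands. The
interval comes from 1000 bootstrap resamples of *mothers* (children travel
with their mother — resampling is by multiplicity weights over per-mother
sums, so a sibship can never be split), with the normal approximation
`point ± 1.96 x SD(bootstrap totals)`; percentile intervals are available
behind a flag. The band cost differences feeding the extrapolation are the
crude per-band differences in cost rates, matching the pounds-per-child-year
framing, with model-standardized differences available as an option. The
bootstrap recomputes the crude differences rather than refitting models in
each resample: the extrapolated quantity is itself crude, and refitting
would change what is being resampled, not just its variance. Coverage of the
resulting intervals is checked by simulation (300 replicates x 200
resamples, exactly computable generative truth under a flat CPI and a
single flat-cost outcome).

The shipped population table (counts per band, prevalence ~0.21-0.23) is a
synthetic England-scale stand-in.

## What the generator emulates — and what it does not

`simulate_cohort()` generates, per mother: a registration spell (with an 8%
early-termination share and rare deaths), a practice up-to-standard date and
data-collection end, a gamma frailty with variance `overdispersion` (default
0.5) shared by all her children and multiplied by a per-child gamma frailty
(variance 0.25), and per-illness onsets (Bernoulli per illness; defaults sum
to ~34% of mothers with any illness). Each onset is *realised as raw coded
events* under one of the three case pathways, chosen at random, and the
illness then recurs as further qualifying episodes at 0.7 per year until
registration ends — pathway-b mothers recur as same-day symptom+prescription
pairs (they have no diagnosis on record), others as repeat prescriptions
against the historical diagnosis. Non-case mother-illness pairs receive
non-qualifying noise (lone symptoms, lone prescriptions, pairs separated by
more than 91 days). The generator therefore never hands exposure flags to
the pipeline: phenotyping and windowing run on raw events end-to-end, and
the set of qualifying (mother, illness, date) triples the phenotyper should
find is tracked exactly as planted truth, which the tests require to match
the classifier's output identically.

Counts per segment and outcome are gamma-Poisson with mean
`base rate x ratio^exposed x exp(trend x (year-2007)) x person-years x
frailty`; default base rates and ratios are the published per-outcome cohort
values (their event-weighted total-use ratio is 1.268). Prescriptions are
planted per drug category with category-specific ratios (mental/behavioural
highest at 1.77, infections lowest at 1.25), and about 30% of drug codes
carry no specific tariff so the average-cost fallback is exercised at
roughly the published share. Realised events get uniform dates within their
segment; accidental same-day same-type collisions are redrawn so that
deduplicated counts equal planted counts, and deduplication is instead
exercised by explicitly planted duplicates (5% of events by default) plus
pre-follow-up noise events that the counter must drop.

What the generator does *not* emulate — so passing tests say nothing about
these aspects of real data: disease natural history and code semantics
(codes are synthetic tokens), seasonality and day-of-week structure,
informative censoring (dropout is independent of illness and frailty),
multiple registration spells, mother-baby linkage error, band- or
age-varying baseline rates, and any correlation between deprivation and
exposure (IMD is planted uniform, so the IMD adjustment is exercised but
cannot change estimates in synthetic data).

## Problem sizes and numerical choices

The default analysis cohort in `analysis/` uses 6,000 mothers (~11,000
children, ~33,000 person-years); the calibration studies use 20,000 mothers
per replicate for rate-ratio recovery (200 replicates) and 250 mothers per
replicate for bootstrap coverage (300 replicates x 200 resamples) — sizes at
which Monte-Carlo error is small relative to the tolerances being asserted
while a full run of the test suite stays comfortably interactive. Dates are
integer days throughout; calendar arithmetic uses era-based civil-date
algorithms rather than locale-dependent string formatting, so results are
identical across platforms. All randomness flows from a single integer seed
per dataset and per bootstrap; equal seeds give byte-identical CSV output.

## Known limitations

* Rate differences from the NB model are a modelling choice (marginal
  standardization); other standardizations (e.g. to the exposed covariate
  distribution) would give slightly different absolute effects.
* The band-specific estimates come from one interaction model; stratified
  per-band fits (available by filtering records to a band) can differ when
  dispersion truly varies by age.
* The bootstrap treats the tariff tables and population counts as fixed;
  uncertainty in unit costs and prevalence is not propagated.
* Synthetic tariffs, prevalences and population counts are stand-ins: the
  *pipeline* is validated, but its shipped outputs are not estimates of any
  real national cost.
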