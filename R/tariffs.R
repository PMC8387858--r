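# Synthetic tariff and CPI tables. Unit costs are plausible UK magnitudes,
# constant in nominal terms across years (the CPI adjustment still moves
# base-year values); real analyses substitute the published schedules with
# the same schema.

#' Synthetic tariff table
#'
#' One row per (year, outcome, subtype) with the columns `unit_cost`,
#' `per_admission_cost` and `per_bed_day_cost` (blank where not applicable).
#' Primary-care subtypes are `"<consultation_type>|<staff>"` pairs;
#' prescription subtypes are drug codes plus a `"__average__"` fallback row
#' per year; inpatient subtypes are episode types, with bed-day costs only for
#' elective and non-elective admissions; referral, out-patient and emergency
#' rows use the empty subtype (one average unit cost).
#'
#' @param years calendar years to cover.
#' @return data.frame tariff table.
#' @export
default_tariffs <- function(years = 2005:2018) {
  cons <- c("face-to-face", "telephone", "home-visit")
  staff <- c("doctor", "nurse", "health-visitor", "other")
  pc_cost <- matrix(
    c(37, 13, 17, 20,
      22, 8, 10, 12,
      92, 28, 35, 40),
    nrow = 3, byrow = TRUE, dimnames = list(cons, staff)
  )
  pc <- data.frame(
    outcome = "primary_care",
    subtype = as.vector(outer(cons, staff, paste, sep = "|")),
    unit_cost = as.vector(pc_cost),
    per_admission_cost = NA_real_, per_bed_day_cost = NA_real_
  )
  flat <- data.frame(
    outcome = c("referral", "outpatient", "emergency"),
    subtype = "",
    unit_cost = c(45, 120, 138),
    per_admission_cost = NA_real_, per_bed_day_cost = NA_real_
  )
  dc <- default_drug_codes()
  dc <- dc[dc$specific_tariff, ]
  rx_cost <- 3 + 2.5 * seq_len(nrow(dc))
  rx <- data.frame(
    outcome = "prescription",
    subtype = c(dc$drug_code, "__average__"),
    unit_cost = c(rx_cost, 8),
    per_admission_cost = NA_real_, per_bed_day_cost = NA_real_
  )
  inp <- data.frame(
    outcome = "inpatient",
    subtype = c("day-case", "regular-day-night", "elective", "non-elective"),
    unit_cost = NA_real_,
    per_admission_cost = c(698, 412, 3375, 1521),
    per_bed_day_cost = c(NA, NA, 346, 296)
  )
  base <- rbind(pc, flat, rx, inp)
  out <- do.call(rbind, lapply(years, function(y) cbind(year = y, base)))
  rownames(out) <- NULL
  out
}

#' Synthetic CPI table
#'
#' A 2% annual price index with 2017 = 100 (costing only uses index ratios,
#' so the base-year normalisation is immaterial).
#'
#' @param years calendar years to cover.
#' @param annual_growth annual inflation rate.
#' @return data.frame with columns `year`, `index`.
#' @export
default_cpi <- function(years = 2005:2018, annual_growth = 0.02) {
  data.frame(year = years,
             index = 100 * (1 + annual_growth)^(years - CPI_BASE_YEAR))
}
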