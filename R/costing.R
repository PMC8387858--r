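# Tariff-based costing with CPI inflation adjustment to a 2017 base year.
#
# Tariff schema (one CSV): year, outcome, subtype, unit_cost,
# per_admission_cost, per_bed_day_cost. Subtype keys:
#   primary_care  "<consultation_type>|<staff>"
#   prescription  drug code, with a "__average__" row per year as the
#                 fallback when no drug-specific cost exists
#   inpatient     episode type (day-case and regular-day-night rows carry a
#                 per-admission cost; elective / non-elective rows carry
#                 per-admission + per-bed-day costs)
#   others        "" (one average unit cost per year and outcome)

CPI_BASE_YEAR <- 2017L
RX_AVERAGE_KEY <- "__average__"

#' Inflate an amount to the base year
#'
#' `amount * index(base_year) / index(year)`.
#'
#' @param amount numeric amounts.
#' @param year calendar year(s) the amounts are expressed in.
#' @param cpi data.frame with columns `year`, `index`.
#' @param base_year base year (default 2017); must be present in `cpi`.
#' @return numeric amounts in base-year terms.
#' @export
inflate <- function(amount, year, cpi, base_year = CPI_BASE_YEAR) {
  idx <- setNames(cpi$index, cpi$year)
  if (!as.character(base_year) %in% names(idx)) {
    stop("configuration error: CPI base year ", base_year, " missing", call. = FALSE)
  }
  iy <- idx[as.character(year)]
  if (anyNA(iy)) {
    stop("configuration error: CPI index missing for year(s) ",
         paste(unique(year[is.na(iy)]), collapse = ", "), call. = FALSE)
  }
  amount * idx[[as.character(base_year)]] / unname(iy)
}

#' Cost healthcare-use events
#'
#' Attaches a base-year cost to each event. Primary care, referral,
#' out-patient and emergency events take the year's unit cost for their
#' subtype; prescriptions take the drug-specific cost, falling back to the
#' year's average prescription cost when none exists; day-case and
#' regular-day-night admissions take a per-admission cost; elective and
#' non-elective admissions are costed as per-admission + per-bed-day x length
#' of stay (or per-bed-day x max(length of stay, 1) with
#' `admission_formula = "bed_day_only"`). All costs are inflated to the base
#' year.
#'
#' @param events data.frame of use events.
#' @param tariffs tariff table (see [default_tariffs()]).
#' @param cpi CPI table (`year`, `index`).
#' @param admission_formula `"additive"` (default) or `"bed_day_only"`.
#' @param base_year CPI base year.
#' @return `events` with a `cost` column (base-year currency units).
#' @export
cost_events <- function(events, tariffs, cpi, admission_formula = c("additive", "bed_day_only"),
                        base_year = CPI_BASE_YEAR) {
  admission_formula <- match.arg(admission_formula)
  ev <- as.data.table(events)
  if (nrow(ev) == 0L) {
    ev[, cost := numeric()]
    return(setDF(ev))
  }
  tr <- as.data.table(tariffs)
  ev[, date := as_date(date)]
  ev[, year := year_of(date)]
  ev[, subtype := ""]
  ev[outcome == "primary_care",
     subtype := paste(consultation_type, staff, sep = "|")]
  ev[outcome == "prescription", subtype := as.character(drug_code)]
  ev[outcome == "inpatient", subtype := as.character(episode_type)]

  tl <- tr[, .(year, outcome, subtype, unit_cost, per_admission_cost,
               per_bed_day_cost)]
  ev <- tl[ev, on = .(year, outcome, subtype)]

  # prescription fallback: the year's average unit cost
  miss_rx <- ev[, outcome == "prescription" & is.na(unit_cost)]
  if (any(miss_rx)) {
    avg <- tl[outcome == "prescription" & subtype == RX_AVERAGE_KEY,
              .(year, avg_cost = unit_cost)]
    ev[miss_rx, unit_cost := avg$avg_cost[match(year, avg$year)]]
    if (anyNA(ev$unit_cost[which(miss_rx)])) {
      bad <- unique(ev$year[which(miss_rx)][is.na(ev$unit_cost[which(miss_rx)])])
      stop("costing error: no average prescription cost for year(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }

  ev[, cost := NA_real_]
  inp <- ev$outcome == "inpatient"
  ev[!inp, cost := unit_cost]
  if (any(inp)) {
    los_dep <- inp & ev$subtype %in% c("elective", "non-elective")
    if (admission_formula == "additive") {
      ev[los_dep, cost := per_admission_cost +
           per_bed_day_cost * as.numeric(length_of_stay)]
    } else {
      ev[los_dep, cost := per_bed_day_cost *
           pmax(as.numeric(length_of_stay), 1)]
    }
    ev[inp & !los_dep, cost := per_admission_cost]
  }
  if (anyNA(ev$cost)) {
    bad <- unique(ev[is.na(cost), paste(year, outcome, subtype, sep = "/")])
    stop("costing error: missing tariff for key(s): ",
         paste(head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  ev[, cost := inflate(cost, year, cpi, base_year)]
  ev[, c("unit_cost", "per_admission_cost", "per_bed_day_cost") := NULL]
  setDF(ev)
}

#' @rdname cost_events
#' @export
cost_event <- function(events, tariffs, cpi, ...) {
  cost_events(events, tariffs, cpi, ...)$cost
}

#' Per-segment cost records
#'
#' Deduplicates events with the same rule as [count_events()], costs them with
#' [cost_events()] and sums base-year costs per person-time segment (zero for
#' eventless segments), with the cost rate in pounds per child per year.
#'
#' @inheritParams cost_events
#' @param segments data.frame from [assign_exposure()].
#' @param dedup_level passed to the deduplication rule.
#' @return data.frame of cost records: segment identifiers and covariates,
#'   `cost`, `cost_rate` (= cost / person-years).
#' @export
cost_rates <- function(events, segments, tariffs, cpi,
                       dedup_level = "subtype",
                       admission_formula = "additive",
                       base_year = CPI_BASE_YEAR) {
  seg <- prepare_segments(segments)
  ev <- prep_events(events, seg, dedup_level)
  n_dropped <- attr(ev, "n_dropped")
  if (nrow(ev)) {
    ev <- as.data.table(cost_events(ev, tariffs, cpi,
                                    admission_formula = admission_formula,
                                    base_year = base_year))
    costs <- ev[, .(cost = sum(cost)), by = seg_id]
  } else {
    costs <- data.table(seg_id = integer(), cost = numeric())
  }
  seg_cols <- setdiff(names(seg), c("seg_start", "seg_end", "seg_days",
                                    "band_start_date"))
  out <- costs[seg[, ..seg_cols], on = "seg_id"]
  out[is.na(cost), cost := 0]
  out[, cost_rate := cost / person_years]
  out[, seg_id := NULL]
  out <- setDF(out)
  setattr(out, "n_dropped", n_dropped)
  out
}
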