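# Cohort construction: follow-up intervals, eligibility, age-band person-time
# and per-band exposure flags.

DEFAULT_STUDY_START <- as.Date("2007-04-01")
DEFAULT_STUDY_END <- as.Date("2017-07-31")

#' Child follow-up intervals
#'
#' Follow-up starts at the latest of: birth, the practice's up-to-standard
#' date, the child's registration date and the study start. It ends at the
#' earliest of: transfer out (registration end), 18th birthday, child death,
#' mother death, practice data collection end and the study end. Intervals are
#' half-open `[start, end)`; an interval with `end <= start` is empty and
#' reported as `NA`.
#'
#' @param children data.frame of child records (see [simulate_cohort()] for
#'   the schema).
#' @param mothers data.frame of mother records (used for the mother's death
#'   date); children whose `mother_id` is unmatched get `NA` mother fields.
#' @param study_start,study_end study window bounds (`Date`).
#' @return `children` with added columns `fu_start`, `fu_end`, `fu_days`
#'   (`NA` where follow-up is empty or the birth date is missing).
#' @export
follow_up_interval <- function(children, mothers,
                               study_start = DEFAULT_STUDY_START,
                               study_end = DEFAULT_STUDY_END) {
  ch <- as.data.table(children)
  mo <- as.data.table(mothers)
  date_cols <- intersect(
    c("birth_date", "death_date", "registration_start", "registration_end",
      "practice_uts_date", "practice_collection_end"),
    names(ch)
  )
  for (cc in date_cols) set(ch, j = cc, value = as_date(ch[[cc]]))
  mo_death <- mo[, .(mother_id = as.character(mother_id),
                     mother_death = as_date(death_date))]
  ch[, mother_id := as.character(mother_id)]
  ch <- mo_death[ch, on = "mother_id"]

  ch[, fu_start := pmax_date(birth_date, practice_uts_date,
                             registration_start, rep(study_start, .N))]
  ch[, fu_end := pmin_date(registration_end, add_years(birth_date, 18L),
                           death_date, mother_death,
                           practice_collection_end, rep(study_end, .N))]
  ch[is.na(birth_date), c("fu_start", "fu_end") := .(as.Date(NA), as.Date(NA))]
  ch[!is.na(fu_start) & !is.na(fu_end) & fu_end <= fu_start,
     c("fu_start", "fu_end") := .(as.Date(NA), as.Date(NA))]
  ch[, fu_days := as.numeric(fu_end - fu_start)]
  ch[, mother_death := NULL]
  setDF(ch)
}

#' Apply cohort eligibility rules
#'
#' Exclusion rules, applied in a fixed order with a first-failure tally:
#' missing birth date; unmatched mother; no HES linkage; follow-up shorter
#' than 30.5 days; mother not registered at an up-to-standard practice at the
#' child's follow-up start; mother with less than 2 years (730 days) of
#' registration before or after the child's follow-up start.
#'
#' @inheritParams follow_up_interval
#' @param min_days minimum follow-up duration in days (inclusive).
#' @return list with `children` (eligible, including follow-up columns),
#'   `exclusions` (data.frame `reason`, `n`, in order of application) and
#'   `n_eligible`.
#' @export
apply_eligibility <- function(children, mothers,
                              study_start = DEFAULT_STUDY_START,
                              study_end = DEFAULT_STUDY_END,
                              min_days = MIN_FOLLOW_UP_DAYS) {
  ch <- as.data.table(
    follow_up_interval(children, mothers, study_start, study_end)
  )
  mo <- as.data.table(mothers)
  mo <- mo[, .(mother_id = as.character(mother_id),
               m_reg_start = as_date(registration_start),
               m_reg_end = as_date(registration_end),
               m_uts = as_date(practice_uts_date))]
  ch[, mother_id := as.character(mother_id)]
  ch <- mo[ch, on = "mother_id"]

  reasons <- c("missing_birth_date", "no_mother_record", "no_hes_linkage",
               "follow_up_lt_30.5_days", "mother_not_uts_at_start",
               "mother_lt_2y_data")
  ch[, reason := NA_character_]
  ch[is.na(birth_date), reason := "missing_birth_date"]
  ch[is.na(reason) & is.na(m_reg_start), reason := "no_mother_record"]
  ch[is.na(reason) & !hes_linked, reason := "no_hes_linkage"]
  ch[is.na(reason) & (is.na(fu_days) | fu_days < min_days),
     reason := "follow_up_lt_30.5_days"]
  # mother registered at an up-to-standard practice on the fu start date
  ch[is.na(reason),
     uts_ok := m_reg_start <= fu_start & fu_start < m_reg_end &
       m_uts <= fu_start]
  ch[is.na(reason) & !uts_ok, reason := "mother_not_uts_at_start"]
  ch[is.na(reason),
     cover_ok := m_reg_start <= fu_start - TWO_YEARS_DAYS &
       m_reg_end >= fu_start + TWO_YEARS_DAYS]
  ch[is.na(reason) & !cover_ok, reason := "mother_lt_2y_data"]

  tally <- ch[!is.na(reason), .N, by = reason]
  exclusions <- data.frame(reason = reasons,
                           n = tally$N[match(reasons, tally$reason)])
  exclusions$n[is.na(exclusions$n)] <- 0L

  keep <- ch[is.na(reason)]
  keep[, c("reason", "uts_ok", "cover_ok", "m_reg_start", "m_reg_end",
           "m_uts") := NULL]
  list(children = setDF(keep), exclusions = exclusions,
       n_eligible = nrow(keep))
}

#' Split follow-up into age-band person-time segments
#'
#' Splits each child's follow-up interval at the calendrical 1st, 5th, 10th
#' and 14th birthdays into the five age bands. Bands are half-open in age, so
#' segments are disjoint and their person-years sum exactly to the follow-up
#' duration. `period` is the calendar year in which the segment starts.
#'
#' @param children_fu data.frame from [follow_up_interval()] or
#'   [apply_eligibility()] (rows with `NA` follow-up are dropped).
#' @return data.frame of person-time segments: `child_id`, `mother_id`,
#'   `age_band`, `band_start_date`, `seg_start`, `seg_end`, `seg_days`,
#'   `person_years`, `period`, plus `sex`, `imd_quintile` when present.
#' @export
split_age_bands <- function(children_fu) {
  ch <- as.data.table(children_fu)
  ch <- ch[!is.na(fu_start)]
  bands <- as.data.table(age_bands())
  out <- ch[rep(seq_len(.N), each = nrow(bands))]
  out[, age_band := rep(bands$age_band, nrow(ch))]
  lower <- rep(bands$lower, nrow(ch))
  upper <- rep(bands$upper, nrow(ch))
  out[, band_start_date := add_years(as_date(birth_date), lower)]
  out[, band_end_date := add_years(as_date(birth_date), upper)]
  out[, seg_start := pmax_date(fu_start, band_start_date)]
  out[, seg_end := pmin_date(fu_end, band_end_date)]
  out <- out[seg_end > seg_start]
  out[, seg_days := as.numeric(seg_end - seg_start)]
  out[, person_years := days_to_years(seg_days)]
  out[, period := year_of(seg_start)]
  keep <- intersect(
    c("child_id", "mother_id", "age_band", "band_start_date", "seg_start",
      "seg_end", "seg_days", "person_years", "period", "sex", "imd_quintile"),
    names(out)
  )
  out <- out[, ..keep]
  setorder(out, child_id, seg_start)
  setDF(out)
}

#' Attach per-band exposure flags to person-time segments
#'
#' A child is exposed for an age band if the mother has a case determination
#' for a member illness inside the band's exposure window. In `main` mode the
#' window is the closed interval from 2 years (730 days) before the band start
#' to the end of the child's observed segment; in `sensitivity` mode it closes
#' the day before the band starts (exposure during the band itself is
#' ignored), so the sensitivity-mode exposed set is always a subset of the
#' main-mode set.
#'
#' @param segments data.frame from [split_age_bands()].
#' @param determinations data.frame from [classify_cases()].
#' @param mode `"main"` or `"sensitivity"`.
#' @param categories named list of illness-token vectors (default
#'   [exposure_categories()]); one logical column `exposed_<name>` is added
#'   per category.
#' @return `segments` with the exposure flag columns added.
#' @export
assign_exposure <- function(segments, determinations, mode = c("main", "sensitivity"),
                            categories = exposure_categories()) {
  mode <- match.arg(mode)
  seg <- as.data.table(segments)
  seg[, band_start_date := as_date(band_start_date)]
  seg[, seg_end := as_date(seg_end)]
  seg[, lo := band_start_date - TWO_YEARS_DAYS]
  seg[, hi := if (mode == "main") seg_end else band_start_date - 1L]
  seg[, seg_id := .I]
  det <- as.data.table(determinations)
  if (nrow(det)) {
    det <- det[, .(mother_id = as.character(mother_id), illness,
                   case_date = as_date(case_date))]
  }
  seg[, mother_id := as.character(mother_id)]
  for (nm in names(categories)) {
    colnm <- paste0("exposed_", nm)
    if (nrow(det) == 0L) {
      seg[, (colnm) := FALSE]
      next
    }
    dd <- unique(det[illness %in% categories[[nm]], .(mother_id, case_date)])
    setkey(dd, mother_id, case_date)
    # latest determination on or before the window end; exposed iff it also
    # falls on or after the window start
    last_det <- dd[seg[, .(mother_id, hi)],
                   on = .(mother_id, case_date <= hi), mult = "last",
                   x.case_date]
    seg[, (colnm) := !is.na(last_det) & last_det >= lo]
  }
  seg[, c("lo", "hi", "seg_id") := NULL]
  setDF(seg)
}
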