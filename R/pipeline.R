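# End-to-end glue: raw tables -> phenotype -> eligible cohort -> exposed
# person-time -> counts/costs -> effect estimates.

#' Build exposed person-time segments from raw tables
#'
#' Runs phenotyping, eligibility, age-band splitting and exposure assignment.
#'
#' @param dataset list with `children`, `mothers`, `clinical_events`,
#'   `codelist` (as from [simulate_cohort()] or [read_dataset()]).
#' @param mode exposure window mode, `"main"` or `"sensitivity"`.
#' @param study_start,study_end study window.
#' @param require_hes if `FALSE`, the HES-linkage rule is waived and the
#'   cohort restricted to unlinked children (the no-linkage comparison);
#'   only primary-care outcomes are then meaningful.
#' @return list: `segments` (with exposure flags), `determinations`,
#'   `exclusions`.
#' @export
build_segments <- function(dataset, mode = "main",
                           study_start = DEFAULT_STUDY_START,
                           study_end = DEFAULT_STUDY_END,
                           require_hes = TRUE) {
  det <- classify_cases(dataset$clinical_events, dataset$codelist)
  children <- dataset$children
  if (!require_hes) {
    children <- children[!children$hes_linked, ]
    children$hes_linked <- TRUE  # waive the rule for the unlinked comparison
  }
  elig <- apply_eligibility(children, dataset$mothers, study_start, study_end)
  seg <- split_age_bands(elig$children)
  seg <- assign_exposure(seg, det, mode = mode)
  list(segments = seg, determinations = det, exclusions = elig$exclusions)
}

#' Run the full estimation pipeline on a dataset
#'
#' Segments, counts and (optionally) per-outcome effect estimates for one
#' exposure category.
#'
#' @inheritParams build_segments
#' @param outcomes outcomes to fit (default the six use outcomes plus
#'   `"total"`).
#' @param category exposure category.
#' @param adjust_imd adjust rate models for IMD quintile.
#' @param fit fit the models (set `FALSE` to stop after counting).
#' @param ... passed on to [fit_cell()].
#' @return list: `segments`, `counts`, `estimates` (stacked [fit_cell()]
#'   output with an `outcome` column), `exclusions`.
#' @export
run_pipeline <- function(dataset, mode = "main", outcomes = c(USE_OUTCOMES, "total"),
                         category = "any", adjust_imd = FALSE, fit = TRUE,
                         study_start = DEFAULT_STUDY_START,
                         study_end = DEFAULT_STUDY_END, ...) {
  built <- build_segments(dataset, mode, study_start, study_end)
  counts <- count_events(dataset$use_events, built$segments)
  estimates <- NULL
  if (fit) {
    cdt <- as.data.table(counts)
    est <- lapply(outcomes, function(o) {
      rows <- fit_cell(cdt[outcome == o], category = category,
                       adjust_imd = adjust_imd, ...)
      cbind(outcome = o, rows)
    })
    estimates <- do.call(rbind, est)
  }
  list(segments = built$segments, counts = counts, estimates = estimates,
       exclusions = built$exclusions)
}
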