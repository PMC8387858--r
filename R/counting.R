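# Healthcare-use event counting with same-day deduplication.
#
# "Same type on the same date counted once": the dedup key is
# (child, date, outcome, subtype), where the subtype is the
# consultation-by-staff pair for primary care, the drug code for
# prescriptions, and empty elsewhere — costing differs by subtype, so
# collapsing across subtypes would corrupt costs.

USE_OUTCOMES <- c("primary_care", "prescription", "referral", "outpatient",
                  "inpatient", "emergency")

# integer dedup key per event row (surrogate for the subtype)
event_dedup_key <- function(ev, dedup_level = c("subtype", "outcome")) {
  dedup_level <- match.arg(dedup_level)
  n <- nrow(ev)
  if (dedup_level == "outcome") return(integer(n))
  k <- integer(n)
  pc <- which(ev$outcome == "primary_care")
  if (length(pc)) {
    cons <- chmatch(ev$consultation_type[pc],
                    c("face-to-face", "telephone", "home-visit"))
    stf <- chmatch(ev$staff[pc],
                   c("doctor", "nurse", "health-visitor", "other"))
    cons[is.na(cons)] <- 9L
    stf[is.na(stf)] <- 9L
    k[pc] <- cons * 10L + stf
  }
  rxp <- which(ev$outcome == "prescription")
  if (length(rxp)) {
    drugs <- as.character(ev$drug_code[rxp])
    k[rxp] <- 100L + chmatch(drugs, unique(drugs))
  }
  k
}

# working copy of a segment table with a row id and typed key columns
prepare_segments <- function(segments) {
  seg <- copy(as.data.table(segments))
  seg[, seg_id := .I]
  seg[, child_id := as.character(child_id)]
  seg[, seg_start := as_date(seg_start)]
  seg[, seg_end := as_date(seg_end)]
  seg
}

# deduplicate (same child, date, outcome, subtype counted once) and assign
# each event to the unique person-time segment containing its date (half-open
# [seg_start, seg_end)); events outside all segments are dropped, their count
# attached as the n_dropped attribute
prep_events <- function(events, seg, dedup_level = "subtype", cols = NULL) {
  ev <- as.data.table(events)
  if (!is.null(cols)) {
    keep <- intersect(unique(c("child_id", "date", "outcome", cols)),
                      names(ev))
    ev <- ev[, ..keep]
  } else {
    ev <- copy(ev)
  }
  if (nrow(ev) == 0L) {
    ev[, seg_id := integer()]
    setattr(ev, "n_dropped", 0L)
    return(ev)
  }
  children <- unique(seg$child_id)
  ev[, date := as_date(date)]
  # integer surrogates keep the radix passes cheap
  ev[, cid := chmatch(as.character(child_id), children)]
  ev[, oid := chmatch(outcome, unique(outcome))]
  ev[, key_ := event_dedup_key(ev, dedup_level)]
  ev <- unique(ev, by = c("cid", "date", "oid", "key_"))
  n_raw <- nrow(ev)
  ev <- ev[!is.na(cid)]
  # rolling join to the latest segment starting on or before the event date,
  # then a bounds check against that segment's end
  skey <- seg[, .(cid = chmatch(child_id, children), seg_start, seg_id,
                  seg_end)]
  setkey(skey, cid, seg_start)
  cand <- skey[ev[, .(cid, date)], on = .(cid, seg_start <= date),
               mult = "last", .(seg_id = x.seg_id, seg_end = x.seg_end)]
  ok <- !is.na(cand$seg_id) & ev$date < cand$seg_end
  ev[, seg_id := fifelse(ok, cand$seg_id, NA_integer_)]
  n_dropped <- (n_raw - nrow(ev)) + sum(is.na(ev$seg_id))
  out <- ev[!is.na(seg_id)]
  out[, c("cid", "oid", "key_") := NULL]
  setattr(out, "n_dropped", n_dropped)
  out
}

#' Count healthcare-use events per person-time segment
#'
#' Deduplicates events (same child, date, outcome and subtype counted once),
#' assigns each to the unique segment containing its date, and returns one
#' count record per segment and outcome, including zero counts and a `total`
#' record summing the six outcomes. Events dated outside all segments are
#' dropped; their number is attached as the `n_dropped` attribute.
#'
#' @param events data.frame of use events (`child_id`, `date`, `outcome` plus
#'   outcome-specific subtype columns).
#' @param segments data.frame from [assign_exposure()].
#' @param dedup_level `"subtype"` (default) or `"outcome"` (collapse all
#'   same-day events of the same outcome regardless of subtype).
#' @return data.frame of count records: segment identifiers and covariates,
#'   `outcome` (six outcomes plus `"total"`), `count`.
#' @export
count_events <- function(events, segments, dedup_level = "subtype") {
  seg <- prepare_segments(segments)
  ev <- prep_events(events, seg, dedup_level,
                    cols = c("consultation_type", "staff", "drug_code"))
  n_dropped <- attr(ev, "n_dropped")

  outcomes <- USE_OUTCOMES
  if (nrow(ev)) outcomes <- union(outcomes, unique(ev$outcome))
  grid <- CJ(seg_id = seg$seg_id, outcome = outcomes)
  if (nrow(ev)) {
    tab <- ev[, .(count = .N), by = .(seg_id, outcome)]
    grid <- tab[grid, on = .(seg_id, outcome)]
  } else {
    grid[, count := 0L]
  }
  grid[is.na(count), count := 0L]
  totals <- grid[, .(outcome = "total", count = sum(count)), by = seg_id]
  grid <- rbind(grid, totals, use.names = TRUE)

  seg_cols <- setdiff(names(seg), c("seg_start", "seg_end", "seg_days",
                                    "band_start_date"))
  out <- merge(seg[, ..seg_cols], grid, by = "seg_id")
  out[, seg_id := NULL]
  setorder(out, child_id, age_band, outcome)
  out <- setDF(out)
  setattr(out, "n_dropped", n_dropped)
  out
}

#' Prescription rates by drug category
#'
#' Deduplicated prescription rates per drug category, split by an exposure
#' flag, with the crude exposed/unexposed rate ratio (the two-group rate path
#' of the inference module). Prescriptions with a missing category are
#' bucketed as `"uncategorised"`.
#'
#' @inheritParams count_events
#' @param category exposure category name (flag column `exposed_<category>`
#'   must exist on `segments`).
#' @return data.frame: `drug_category`, events and person-years per arm,
#'   `rate_exposed`, `rate_unexposed`, `rate_ratio`.
#' @export
tabulate_by_drug_category <- function(events, segments, category = "any",
                                      dedup_level = "subtype") {
  seg <- prepare_segments(segments)
  flag <- paste0("exposed_", category)
  stopifnot(flag %in% names(seg))
  ev <- as.data.table(events)
  ev <- ev[outcome == "prescription"]
  empty <- data.frame(
    drug_category = character(), n_exposed = integer(),
    n_unexposed = integer(), py_exposed = numeric(), py_unexposed = numeric(),
    rate_exposed = numeric(), rate_unexposed = numeric(),
    rate_ratio = numeric()
  )
  if (nrow(ev) == 0L) return(empty)
  ev <- prep_events(ev, seg, dedup_level)
  if (nrow(ev) == 0L) return(empty)
  ev[, drug_category := as.character(drug_category)]
  ev[is.na(drug_category) | drug_category == "", drug_category := "uncategorised"]
  ev[, exposed := seg[[flag]][seg_id]]
  py <- seg[, .(py = sum(person_years)), by = .(exposed = get(flag))]
  py_e <- sum(py$py[py$exposed])
  py_u <- sum(py$py[!py$exposed])
  tab <- ev[, .(n_exposed = sum(exposed), n_unexposed = sum(!exposed)),
            by = drug_category]
  tab[, py_exposed := py_e]
  tab[, py_unexposed := py_u]
  tab[, rate_exposed := n_exposed / py_exposed]
  tab[, rate_unexposed := n_unexposed / py_unexposed]
  tab[, rate_ratio := rate_exposed / rate_unexposed]
  setorder(tab, -rate_ratio)
  setDF(tab)
}
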