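# Maternal mental illness phenotyping from coded primary-care events.
#
# A mother is a case of an illness on a given date through one of three
# pathways:
#   (a) a diagnosis event, on its own date;
#   (b) a prescription within `rx_symptom_window_days` (default 91, inclusive)
#       of a symptom of the same illness, on the later date of the pair;
#   (c) a prescription or symptom with any strictly earlier diagnosis of the
#       same illness, on its own date.

MMI_ILLNESSES <- c(
  "nonaffective_psychosis", "affective_psychosis", "depression", "anxiety",
  "eating_disorder", "personality_disorder", "substance_misuse",
  "alcohol_misuse"
)

EVENT_CLASSES <- c("diagnosis", "symptom", "prescription")

PATHWAY_LEVELS <- c("diagnosis", "rx_near_symptom", "event_with_history")

#' Maternal mental illness exposure categories
#'
#' The four exposure groupings: common mental illness (depression, anxiety),
#' serious mental illness (non-affective or affective psychosis), addiction
#' (substance or alcohol misuse), and any of the eight illnesses. Eating and
#' personality disorders appear only under `any`. Categories are not mutually
#' exclusive: a child can be exposed under several at once.
#'
#' @return named list of character vectors of member illness tokens.
#' @export
exposure_categories <- function() {
  list(
    any = MMI_ILLNESSES,
    cmi = c("depression", "anxiety"),
    smi = c("nonaffective_psychosis", "affective_psychosis"),
    addiction = c("substance_misuse", "alcohol_misuse")
  )
}

#' Synthetic code list
#'
#' A fixture code list mapping opaque synthetic tokens to the eight illnesses
#' and three event classes (two codes per illness per class). Real analyses
#' substitute clinically curated code lists with the same schema.
#'
#' @return data.frame with columns `code`, `illness`, `event_class`.
#' @export
default_codelist <- function() {
  abbr <- c(
    nonaffective_psychosis = "NAP", affective_psychosis = "AFP",
    depression = "DEP", anxiety = "ANX", eating_disorder = "EAT",
    personality_disorder = "PER", substance_misuse = "SUB",
    alcohol_misuse = "ALC"
  )
  cls <- c(diagnosis = "DX", symptom = "SX", prescription = "RX")
  out <- expand.grid(
    illness = MMI_ILLNESSES, event_class = EVENT_CLASSES, idx = 1:2,
    stringsAsFactors = FALSE
  )
  out$code <- paste0(abbr[out$illness], "_", cls[out$event_class], out$idx)
  out[, c("code", "illness", "event_class")]
}

#' Classify mothers as mental illness cases
#'
#' Applies the three case pathways to a mother's coded clinical events and
#' emits one case determination per (mother, illness, qualifying date). When a
#' date qualifies through several pathways the most direct one is kept
#' (diagnosis, then prescription-near-symptom, then event-with-history).
#' Unknown codes are ignored; their count is attached as the
#' `n_unknown_codes` attribute.
#'
#' @param events data.frame with columns `patient_id`, `date`, `code`.
#' @param codelist data.frame with columns `code`, `illness`, `event_class`.
#' @param rx_symptom_window_days inclusive day window for pathway (b).
#' @param symmetric if `TRUE` (default) the prescription may precede or follow
#'   the symptom; if `FALSE`, only a prescription on or after the symptom date
#'   qualifies.
#' @param registrations optional data.frame (`patient_id`,
#'   `registration_start`, `registration_end`); events dated outside the
#'   owner's registration raise a warning but are retained.
#' @return data.frame with columns `mother_id`, `illness`, `case_date`,
#'   `pathway`, ordered by mother, illness, date.
#' @export
classify_cases <- function(events, codelist, rx_symptom_window_days = 91L,
                           symmetric = TRUE, registrations = NULL) {
  if (!is.data.frame(codelist) || nrow(codelist) == 0L) {
    stop("configuration error: the code list is empty", call. = FALSE)
  }
  stopifnot(all(c("code", "illness", "event_class") %in% names(codelist)))
  empty <- data.table(
    mother_id = character(), illness = character(),
    case_date = as.Date(character()), pathway = character()
  )
  ev <- as.data.table(events)
  if (nrow(ev) == 0L) {
    out <- setDF(empty)
    attr(out, "n_unknown_codes") <- 0L
    return(out)
  }
  ev <- ev[, .(patient_id = as.character(patient_id), date = as_date(date),
               code = as.character(code))]
  cl <- as.data.table(codelist)

  if (!is.null(registrations)) {
    reg <- as.data.table(registrations)
    chk <- reg[ev, on = c(patient_id = "patient_id")]
    bad <- chk[!is.na(registration_start) &
                 (date < as_date(registration_start) |
                    date >= as_date(registration_end)), .N]
    if (bad > 0L) {
      warning(sprintf("%d event(s) dated outside the owner's registration; retained", bad))
    }
  }

  n_unknown <- ev[!code %in% cl$code, .N]
  res <- merge(ev, cl, by = "code", allow.cartesian = TRUE)

  dx <- res[event_class == "diagnosis"]
  sx <- res[event_class == "symptom"]
  rx <- res[event_class == "prescription"]

  det <- list(empty)

  if (nrow(dx)) {
    det$a <- dx[, .(mother_id = patient_id, illness, case_date = date,
                    pathway = "diagnosis")]
  }

  if (nrow(rx) && nrow(sx)) {
    w <- as.integer(rx_symptom_window_days)
    rx2 <- rx[, .(patient_id, illness, rx_date = date)]
    rx2[, lo := rx_date - w]
    rx2[, hi := if (symmetric) rx_date + w else rx_date]
    sx2 <- sx[, .(patient_id, illness, sx_date = date)]
    pairs <- sx2[rx2,
      on = .(patient_id, illness, sx_date >= lo, sx_date <= hi),
      .(patient_id, illness, rx_date, sx_date = x.sx_date),
      nomatch = NULL, allow.cartesian = TRUE
    ]
    if (nrow(pairs)) {
      det$b <- pairs[, .(mother_id = patient_id, illness,
                         case_date = pmax(rx_date, sx_date),
                         pathway = "rx_near_symptom")]
    }
  }

  if (nrow(dx) && (nrow(rx) || nrow(sx))) {
    first_dx_dt <- dx[, .(first_dx = min(date)), by = .(patient_id, illness)]
    later <- rbind(sx, rx)[first_dx_dt, on = .(patient_id, illness),
                           nomatch = NULL][date > first_dx]
    if (nrow(later)) {
      det$c <- later[, .(mother_id = patient_id, illness, case_date = date,
                         pathway = "event_with_history")]
    }
  }

  out <- rbindlist(det, use.names = TRUE)
  if (nrow(out)) {
    out[, pathway := factor(pathway, levels = PATHWAY_LEVELS)]
    setorder(out, mother_id, illness, case_date, pathway)
    out <- unique(out, by = c("mother_id", "illness", "case_date"))
    out[, pathway := as.character(pathway)]
  }
  out <- setDF(out)
  attr(out, "n_unknown_codes") <- n_unknown
  out
}

#' Is a mother exposed within a window?
#'
#' `TRUE` iff any case determination for an illness in the category has its
#' case date inside the closed window `[window_start, window_end]`.
#'
#' @param determinations data.frame from [classify_cases()].
#' @param category character: one of `names(exposure_categories())`, or a
#'   character vector of illness tokens.
#' @param window_start,window_end closed window bounds (`Date`).
#' @return logical scalar.
#' @export
exposure_in_window <- function(determinations, category, window_start,
                               window_end) {
  window_start <- as_date(window_start)
  window_end <- as_date(window_end)
  if (window_end < window_start) stop("empty exposure window", call. = FALSE)
  members <- if (length(category) == 1L &&
                 category %in% names(exposure_categories())) {
    exposure_categories()[[category]]
  } else {
    category
  }
  d <- as.data.table(determinations)
  if (nrow(d) == 0L) return(FALSE)
  d[, case_date := as_date(case_date)]
  nrow(d[illness %in% members & case_date >= window_start &
           case_date <= window_end]) > 0L
}
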