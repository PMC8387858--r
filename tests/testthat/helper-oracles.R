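# Independent brute-force oracles and small random-input generators. The
# oracles are deliberately naive (nested loops, all-pairs scans) so they share
# no code path with the implementation they check.

# O(n^2) all-pairs case classifier over resolved events
# (data.frame: patient_id, date, illness, event_class)
oracle_classify <- function(resolved, window = 91, symmetric = TRUE) {
  out <- list()
  for (pid in unique(resolved$patient_id)) {
    pe <- resolved[resolved$patient_id == pid, ]
    for (ill in unique(pe$illness)) {
      e <- pe[pe$illness == ill, ]
      dx <- e$date[e$event_class == "diagnosis"]
      sx <- e$date[e$event_class == "symptom"]
      rx <- e$date[e$event_class == "prescription"]
      dets <- list()
      for (d in dx) {
        dets[[length(dets) + 1L]] <- list(date = d, pathway = "diagnosis")
      }
      for (r in rx) {
        for (s in sx) {
          gap <- as.numeric(r - s)
          hit <- if (symmetric) abs(gap) <= window else gap >= 0 && gap <= window
          if (hit) {
            dets[[length(dets) + 1L]] <-
              list(date = max(r, s), pathway = "rx_near_symptom")
          }
        }
      }
      if (length(dx)) {
        for (ev_date in c(sx, rx)) {
          if (any(dx < ev_date)) {
            dets[[length(dets) + 1L]] <-
              list(date = ev_date, pathway = "event_with_history")
          }
        }
      }
      if (length(dets)) {
        dd <- data.frame(
          mother_id = pid, illness = ill,
          case_date = as.Date(vapply(dets, function(x) as.numeric(x$date),
                                     numeric(1)), origin = "1970-01-01"),
          pathway = vapply(dets, function(x) x$pathway, character(1)),
          stringsAsFactors = FALSE
        )
        # one determination per date; keep the most direct pathway
        dd$rank <- match(dd$pathway,
                         c("diagnosis", "rx_near_symptom",
                           "event_with_history"))
        dd <- dd[order(dd$case_date, dd$rank), ]
        dd <- dd[!duplicated(dd$case_date), ]
        out[[length(out) + 1L]] <- dd[, 1:4]
      }
    }
  }
  if (!length(out)) {
    return(data.frame(mother_id = character(), illness = character(),
                      case_date = as.Date(character()),
                      pathway = character()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$mother_id, res$illness, res$case_date), ]
  rownames(res) <- NULL
  res
}

# random coded event records for n mothers (uses the package's synthetic
# code list so codes resolve); gaps concentrated near the 91-day threshold
random_mother_events <- function(n_mothers, max_events = 100,
                                 codelist = default_codelist()) {
  rows <- list()
  for (i in seq_len(n_mothers)) {
    k <- sample.int(max_events, 1L)
    base <- as.Date("2005-01-01") + sample.int(4000, 1L)
    # half the events cluster within +/- 100 days to stress the pair window
    off <- ifelse(runif(k) < 0.5, sample(-100:100, k, replace = TRUE),
                  sample(-2000:2000, k, replace = TRUE))
    rows[[i]] <- data.frame(
      patient_id = sprintf("M%05d", i),
      date = base + off,
      code = sample(codelist$code, k, replace = TRUE),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

# random child records with valid-but-messy dates for follow-up tests
random_children <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  birth <- as.Date("1993-01-01") + sample.int(9000, n, replace = TRUE)
  reg_start <- birth + sample(0:400, n, replace = TRUE)
  reg_end <- reg_start + sample(0:9000, n, replace = TRUE)
  death <- rep(as.Date(NA), n)
  dies <- runif(n) < 0.05
  death[dies] <- birth[dies] + sample.int(7000, sum(dies), replace = TRUE)
  uts <- as.Date("1995-01-01") + sample.int(6000, n, replace = TRUE)
  colend <- as.Date("2010-01-01") + sample.int(4000, n, replace = TRUE)
  data.frame(
    child_id = sprintf("C%06d", seq_len(n)),
    mother_id = sprintf("M%06d", seq_len(n)),
    birth_date = birth, death_date = death,
    sex = "F", imd_quintile = 3L,
    registration_start = reg_start, registration_end = reg_end,
    practice_uts_date = uts, practice_collection_end = colend,
    hes_linked = TRUE, stringsAsFactors = FALSE
  )
}

random_mothers_for <- function(children) {
  n <- nrow(children)
  death <- rep(as.Date(NA), n)
  dies <- runif(n) < 0.05
  death[dies] <- as.Date("2000-01-01") + sample.int(7000, sum(dies),
                                                    replace = TRUE)
  data.frame(
    mother_id = children$mother_id,
    registration_start = children$birth_date - sample.int(6000, n, TRUE),
    registration_end = children$registration_end +
      sample(-1000:2000, n, replace = TRUE),
    death_date = death,
    practice_uts_date = children$practice_uts_date,
    practice_collection_end = children$practice_collection_end,
    stringsAsFactors = FALSE
  )
}

# minimal segment table for counting/costing tests
make_segments <- function(child_id, mother_id = paste0("m", child_id),
                          seg_start, seg_end, age_band = "1-4",
                          exposed_any = FALSE, period = NULL) {
  seg_start <- as.Date(seg_start)
  seg_end <- as.Date(seg_end)
  data.frame(
    child_id = child_id, mother_id = mother_id, age_band = age_band,
    band_start_date = seg_start, seg_start = seg_start, seg_end = seg_end,
    seg_days = as.numeric(seg_end - seg_start),
    person_years = as.numeric(seg_end - seg_start) / 365.25,
    period = if (is.null(period)) year_of(seg_start) else period,
    sex = "F", imd_quintile = 3L, exposed_any = exposed_any,
    stringsAsFactors = FALSE
  )
}

# a bare use event row; NA subtype fields unless supplied
make_event <- function(child_id, date, outcome,
                       consultation_type = NA, staff = NA,
                       episode_type = NA, length_of_stay = NA,
                       drug_code = NA, drug_category = NA) {
  n <- length(child_id)
  rec <- function(x) rep_len(x, n)
  consultation_type <- rec(consultation_type); staff <- rec(staff)
  episode_type <- rec(episode_type); length_of_stay <- rec(length_of_stay)
  drug_code <- rec(drug_code); drug_category <- rec(drug_category)
  data.frame(
    child_id = child_id, date = as.Date(date), outcome = outcome,
    consultation_type = as.character(consultation_type),
    staff = as.character(staff),
    episode_type = as.character(episode_type),
    length_of_stay = as.integer(length_of_stay),
    drug_code = as.character(drug_code),
    drug_category = as.character(drug_category),
    stringsAsFactors = FALSE
  )
}

# segment-level gamma-Poisson count records with mother clustering, for
# inference tests that do not need the full generator
make_count_records <- function(n_mothers, rate_ratio = 1.27, base_rate = 5,
                               overdispersion = 0.5, p_exposed = 0.25,
                               children_per_mother = 2, py = 1) {
  m <- rep(seq_len(n_mothers), each = children_per_mother)
  n <- length(m)
  frailty <- if (overdispersion > 0) {
    rgamma(n_mothers, 1 / overdispersion, scale = overdispersion)[m]
  } else {
    rep(1, n)
  }
  exposed <- rep(runif(n_mothers) < p_exposed, each = children_per_mother)
  person_years <- py * runif(n, 0.5, 1.5)
  mu <- base_rate * ifelse(exposed, rate_ratio, 1) * person_years * frailty
  data.frame(
    child_id = sprintf("c%05d", seq_len(n)),
    mother_id = sprintf("m%05d", m),
    age_band = sample(age_band_levels(), n, replace = TRUE),
    outcome = "total", count = rpois(n, mu), person_years = person_years,
    period = sample(2007:2016, n, replace = TRUE),
    imd_quintile = sample(1:5, n, replace = TRUE),
    exposed_any = exposed, stringsAsFactors = FALSE
  )
}
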