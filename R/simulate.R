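# Synthetic mother-child linked data with the statistical structure the
# analysis assumes: mother-level gamma frailty shared across siblings (with a
# secondary per-child frailty), multiplicative exposure effects on
# overdispersed gamma-Poisson counts, calendar-period effects, planted
# same-day duplicate events, and registration churn. Exposure is planted at
# the mother level as raw coded clinical events realising one of the three
# case pathways, so phenotyping and exposure windowing run end-to-end
# downstream and are never bypassed.

#' Default per-outcome baseline rates and exposure rate ratios
#'
#' Unexposed event rates (events per child per year) and exposed/unexposed
#' rate ratios per healthcare-use outcome, the generator's study conditions.
#' Each entry may be a scalar or a length-5 vector over the age bands.
#'
#' @name sim_defaults
#' @export
default_baseline_rates <- function() {
  list(primary_care = 4.27, prescription = 3.90, referral = 0.30,
       outpatient = 0.76, inpatient = 0.14, emergency = 0.30)
}

#' @rdname sim_defaults
#' @export
default_rate_ratios <- function() {
  list(primary_care = 1.24, prescription = 1.28, referral = 1.30,
       outpatient = 1.30, inpatient = 1.37, emergency = 1.34)
}

#' @rdname sim_defaults
#' @export
default_prescription_categories <- function() {
  data.frame(
    category = c("infections", "respiratory", "mental_behavioural",
                 "gastrointestinal", "musculoskeletal", "gynae_urinary",
                 "dermatological", "other"),
    base_rate = c(0.90, 0.60, 0.15, 0.35, 0.20, 0.10, 0.50, 1.10),
    rate_ratio = c(1.25, 1.35, 1.77, 1.54, 1.45, 1.41, 1.20, 1.15),
    stringsAsFactors = FALSE
  )
}

#' @rdname sim_defaults
#' @export
default_mmi_prevalence <- function() {
  c(depression = 0.20, anxiety = 0.10, nonaffective_psychosis = 0.005,
    affective_psychosis = 0.005, eating_disorder = 0.015,
    personality_disorder = 0.01, substance_misuse = 0.025,
    alcohol_misuse = 0.02)
}

# three synthetic drug codes per category; the *3 codes carry no
# drug-specific tariff, so roughly 30% of prescriptions exercise the
# annual-average fallback
default_drug_codes <- function() {
  cats <- default_prescription_categories()$category
  out <- data.frame(
    drug_code = paste0(rep(toupper(substr(cats, 1L, 3L)), each = 3L), 1:3),
    drug_category = rep(cats, each = 3L),
    share = rep(c(0.4, 0.3, 0.3), length(cats)),
    specific_tariff = rep(c(TRUE, TRUE, FALSE), length(cats)),
    stringsAsFactors = FALSE
  )
  out
}

#' Simulation configuration
#'
#' Validated configuration for [simulate_cohort()]. The defaults are the
#' study conditions the pipeline is tested under: a 2007-04-01 to 2017-07-31
#' study window, births 1993 to mid-2017, per-outcome unexposed rates and
#' exposure rate ratios at published cohort values, gamma mother frailty of
#' variance `overdispersion` shared by siblings (times a secondary per-child
#' gamma frailty), and registration churn via an exponential dropout hazard.
#'
#' @param n_mothers number of mothers.
#' @param mean_children_per_mother expected sibship size (>= 1).
#' @param study_start,study_end study window.
#' @param birth_start,birth_end eligible birth window.
#' @param mmi_prevalence named per-illness case probabilities.
#' @param recurrence_rate expected qualifying illness episodes per year after
#'   onset (the illness recurs on the record until registration or the study
#'   ends; 0 = a single onset event).
#' @param baseline_rate named list of unexposed rates per outcome (scalar or
#'   length-5 by band).
#' @param rate_ratio named list of exposure rate ratios per outcome.
#' @param prescription_categories data.frame (`category`, `base_rate`,
#'   `rate_ratio`) planting prescriptions per drug category (its base rates
#'   replace `baseline_rate$prescription`); `NULL` plants prescriptions as a
#'   single undifferentiated outcome.
#' @param overdispersion mother-level gamma frailty variance (0 = none).
#' @param child_overdispersion secondary per-child gamma frailty variance.
#' @param period_effect_per_year log-scale linear calendar trend in rates.
#' @param duplicate_event_prob probability a realised use event is duplicated
#'   same-day/same-type (exercises deduplication).
#' @param dropout_hazard per-year hazard of transferring out of the practice.
#' @param hes_linked_prob probability a child has HES linkage.
#' @param seed integer RNG seed.
#' @return validated config (class `mmi_sim_config`).
#' @export
sim_config <- function(n_mothers = 2000L,
                       mean_children_per_mother = 1.8,
                       study_start = "2007-04-01",
                       study_end = "2017-07-31",
                       birth_start = "1993-01-01",
                       birth_end = "2017-06-30",
                       mmi_prevalence = default_mmi_prevalence(),
                       recurrence_rate = 0.7,
                       baseline_rate = default_baseline_rates(),
                       rate_ratio = default_rate_ratios(),
                       prescription_categories = default_prescription_categories(),
                       overdispersion = 0.5,
                       child_overdispersion = 0.25,
                       period_effect_per_year = 0,
                       duplicate_event_prob = 0.05,
                       dropout_hazard = 0.10,
                       hes_linked_prob = 0.95,
                       seed = 1L) {
  cfg <- list(
    n_mothers = as.integer(n_mothers),
    mean_children_per_mother = mean_children_per_mother,
    study_start = as_date(study_start), study_end = as_date(study_end),
    birth_start = as_date(birth_start), birth_end = as_date(birth_end),
    mmi_prevalence = mmi_prevalence, recurrence_rate = recurrence_rate,
    baseline_rate = baseline_rate, rate_ratio = rate_ratio,
    prescription_categories = prescription_categories,
    overdispersion = overdispersion,
    child_overdispersion = child_overdispersion,
    period_effect_per_year = period_effect_per_year,
    duplicate_event_prob = duplicate_event_prob,
    dropout_hazard = dropout_hazard, hes_linked_prob = hes_linked_prob,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "mmi_sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  fail <- function(...) {
    stop("config validation error: ", ..., call. = FALSE)
  }
  if (cfg$n_mothers < 1L) fail("n_mothers must be positive")
  if (cfg$mean_children_per_mother < 1) {
    fail("mean_children_per_mother must be >= 1")
  }
  if (cfg$study_end <= cfg$study_start) fail("study window is empty")
  if (cfg$birth_end <= cfg$birth_start) fail("birth window is empty")
  probs <- c(cfg$mmi_prevalence, cfg$duplicate_event_prob,
             cfg$hes_linked_prob)
  if (any(probs < 0 | probs > 1)) fail("probabilities must lie in [0, 1]")
  if (!all(names(cfg$mmi_prevalence) %in% MMI_ILLNESSES)) {
    fail("unknown illness in mmi_prevalence")
  }
  rates <- unlist(cfg$baseline_rate)
  ratios <- unlist(cfg$rate_ratio)
  if (any(rates <= 0)) fail("baseline rates must be positive")
  if (any(ratios <= 0)) fail("rate ratios must be positive")
  if (!is.null(cfg$prescription_categories)) {
    pc <- cfg$prescription_categories
    if (any(pc$base_rate <= 0) || any(pc$rate_ratio <= 0)) {
      fail("prescription category rates and ratios must be positive")
    }
  }
  if (cfg$overdispersion < 0 || cfg$child_overdispersion < 0) {
    fail("overdispersion must be non-negative")
  }
  if (cfg$recurrence_rate < 0) fail("recurrence_rate must be non-negative")
  if (cfg$dropout_hazard < 0) fail("dropout_hazard must be non-negative")
  invisible(cfg)
}

# uniform integer-day draw in [lo, hi] (vectorised, Date in/out)
runif_date <- function(lo, hi) {
  lo <- as.numeric(lo)
  hi <- as.numeric(hi)
  as.Date(lo + floor(runif(length(lo)) * (hi - lo + 1)), origin = "1970-01-01")
}

rgamma_frailty <- function(n, v) {
  if (v <= 0) rep(1, n) else rgamma(n, shape = 1 / v, scale = v)
}

# mother-level illness onsets and the raw clinical events realising them.
# After onset the illness recurs: further qualifying episodes (same-day
# symptom+prescription pairs for pathway-b mothers, who have no diagnosis on
# record; repeat prescriptions, qualifying against the historical diagnosis,
# for the others) arrive at rate `recurrence_rate` per year until the end of
# registration or the study. `truth_det` collects EVERY qualifying date the
# phenotyper should find, so downstream exposure windows can be verified
# against planted truth exactly. Non-case (mother, illness) pairs may receive
# non-qualifying noise: a lone symptom, a lone prescription, or a
# symptom-prescription pair separated by more than 91 days.
simulate_mmi_events <- function(mothers, cfg, codelist) {
  cl <- as.data.table(codelist)
  n <- nrow(mothers)
  reg_start <- mothers$registration_start
  reg_end <- mothers$registration_end
  hi <- pmin_date(reg_end - 1L, rep(cfg$study_end, n))
  lo <- reg_start + 1L
  codes_by <- split(cl$code, paste(cl$illness, cl$event_class))

  pick_code <- function(ill, class_) {
    key <- paste(ill, class_)
    ukey <- unique(key)
    out <- character(length(key))
    for (k in ukey) {
      cand <- codes_by[[k]]
      sel <- key == k
      out[sel] <- cand[1L + floor(runif(sum(sel)) * length(cand))]
    }
    out
  }

  onset_list <- list()
  event_list <- list()
  det_list <- list()
  for (ill in names(cfg$mmi_prevalence)) {
    p <- cfg$mmi_prevalence[[ill]]
    is_case <- runif(n) < p
    idx <- which(is_case & hi > lo)
    if (length(idx)) {
      onset <- runif_date(lo[idx], hi[idx])
      pathway <- sample(PATHWAY_LEVELS, length(idx), replace = TRUE)
      onset_list[[ill]] <- data.table(
        mother_id = mothers$mother_id[idx], illness = ill,
        onset_date = onset, pathway = pathway
      )
      det_list[[paste0(ill, "_onset")]] <- data.table(
        mother_id = mothers$mother_id[idx], illness = ill, case_date = onset
      )
      ev <- list()
      a <- pathway == "diagnosis"
      if (any(a)) {
        ev$a <- data.table(patient_id = mothers$mother_id[idx][a],
                           date = onset[a],
                           code = pick_code(rep(ill, sum(a)), "diagnosis"))
      }
      b <- pathway == "rx_near_symptom"
      if (any(b)) {
        gap <- pmin(floor(runif(sum(b)) * 92),
                    as.numeric(onset[b] - reg_start[idx][b]))
        ev$b_sx <- data.table(patient_id = mothers$mother_id[idx][b],
                              date = onset[b] - gap,
                              code = pick_code(rep(ill, sum(b)), "symptom"))
        ev$b_rx <- data.table(patient_id = mothers$mother_id[idx][b],
                              date = onset[b],
                              code = pick_code(rep(ill, sum(b)), "prescription"))
      }
      cc <- pathway == "event_with_history"
      if (any(cc)) {
        ev$c_dx <- data.table(patient_id = mothers$mother_id[idx][cc],
                              date = onset[cc],
                              code = pick_code(rep(ill, sum(cc)), "diagnosis"))
      }

      # recurrent qualifying episodes from onset to end of observation
      span_years <- pmax(as.numeric(hi[idx] - onset), 0) / DAYS_PER_YEAR
      n_rec <- rpois(length(idx), cfg$recurrence_rate * span_years)
      rec_i <- rep(seq_along(idx), n_rec)
      if (length(rec_i)) {
        rec_date <- runif_date(onset[rec_i] + 1L, hi[idx][rec_i])
        rec_path <- pathway[rec_i]
        det_list[[paste0(ill, "_rec")]] <- data.table(
          mother_id = mothers$mother_id[idx][rec_i], illness = ill,
          case_date = rec_date
        )
        isb <- rec_path == "rx_near_symptom"
        if (any(isb)) {
          # same-day symptom + prescription pair (these mothers have no
          # diagnosis on record, so a lone prescription would not qualify)
          ev$rec_sx <- data.table(
            patient_id = mothers$mother_id[idx][rec_i][isb],
            date = rec_date[isb],
            code = pick_code(rep(ill, sum(isb)), "symptom")
          )
          ev$rec_rx <- data.table(
            patient_id = mothers$mother_id[idx][rec_i][isb],
            date = rec_date[isb],
            code = pick_code(rep(ill, sum(isb)), "prescription")
          )
        }
        if (any(!isb)) {
          # repeat prescription, qualifying against the historical diagnosis
          ev$rec_hx <- data.table(
            patient_id = mothers$mother_id[idx][rec_i][!isb],
            date = rec_date[!isb],
            code = pick_code(rep(ill, sum(!isb)), "prescription")
          )
        }
      }
      event_list[[ill]] <- rbindlist(ev, use.names = TRUE)
    }

    # noise for non-case mothers of this illness: lone symptom, lone
    # prescription, or a symptom-prescription pair separated by > 91 days;
    # none of these can satisfy a case pathway
    nidx <- which(!is_case & hi > lo + 400L)
    if (length(nidx)) {
      type <- sample(c("none", "sx", "rx", "pair"), length(nidx),
                     replace = TRUE, prob = c(0.84, 0.08, 0.05, 0.03))
      lone <- nidx[type %in% c("sx", "rx")]
      if (length(lone)) {
        cls <- ifelse(type[type %in% c("sx", "rx")] == "sx",
                      "symptom", "prescription")
        event_list[[paste0(ill, "_noise")]] <- data.table(
          patient_id = mothers$mother_id[lone],
          date = runif_date(lo[lone], hi[lone]),
          code = pick_code(rep(ill, length(lone)), cls)
        )
      }
      pr <- nidx[type == "pair"]
      if (length(pr)) {
        gap <- 92L + floor(runif(length(pr)) * 274)
        ok <- as.numeric(hi[pr] - lo[pr]) > gap
        pr <- pr[ok]
        gap <- gap[ok]
        if (length(pr)) {
          d_rx <- runif_date(lo[pr] + gap, hi[pr])
          event_list[[paste0(ill, "_noisepair")]] <- rbind(
            data.table(patient_id = mothers$mother_id[pr], date = d_rx,
                       code = pick_code(rep(ill, length(pr)), "prescription")),
            data.table(patient_id = mothers$mother_id[pr], date = d_rx - gap,
                       code = pick_code(rep(ill, length(pr)), "symptom"))
          )
        }
      }
    }
  }
  onsets <- rbindlist(onset_list, use.names = TRUE)
  if (nrow(onsets) == 0L) {
    onsets <- data.table(mother_id = character(), illness = character(),
                         onset_date = as.Date(character()),
                         pathway = character())
  }
  truth_det <- rbindlist(det_list, use.names = TRUE)
  if (nrow(truth_det) == 0L) {
    truth_det <- data.table(mother_id = character(), illness = character(),
                            case_date = as.Date(character()))
  } else {
    truth_det <- unique(truth_det, by = c("mother_id", "illness", "case_date"))
    setorder(truth_det, mother_id, illness, case_date)
  }
  events <- rbindlist(event_list, use.names = TRUE)
  if (nrow(events) == 0L) {
    events <- data.table(patient_id = character(),
                         date = as.Date(character()), code = character())
  }
  setorder(events, patient_id, date, code)
  list(onsets = onsets, truth_det = truth_det, clinical_events = events)
}

# the per-cell planting table: one row per (outcome, subcategory, band) with
# base rate and exposure rate ratio
build_plant_table <- function(cfg) {
  bands <- age_band_levels()
  expand_entry <- function(x) rep_len(unlist(x), length(bands))
  rows <- list()
  for (o in names(cfg$baseline_rate)) {
    if (o == "prescription" && !is.null(cfg$prescription_categories)) next
    rows[[o]] <- data.table(
      outcome = o, subcat = "", age_band = bands,
      base_rate = expand_entry(cfg$baseline_rate[[o]]),
      rate_ratio = expand_entry(cfg$rate_ratio[[o]])
    )
  }
  if (!is.null(cfg$prescription_categories) &&
      "prescription" %in% names(cfg$baseline_rate)) {
    pc <- cfg$prescription_categories
    for (i in seq_len(nrow(pc))) {
      rows[[paste0("rx_", pc$category[i])]] <- data.table(
        outcome = "prescription", subcat = pc$category[i], age_band = bands,
        base_rate = pc$base_rate[i], rate_ratio = pc$rate_ratio[i]
      )
    }
  }
  rbindlist(rows)
}

#' Simulate a mother-child linked dataset
#'
#' Generates mothers (with registration spells, sibship frailties and planted
#' illness onsets realised as raw coded clinical events), children (with
#' registration churn, HES-linkage flags and demographics), and per-segment
#' healthcare-use counts that are gamma-Poisson: mean = baseline rate x rate
#' ratio^exposed x calendar trend x person-years x mother frailty x child
#' frailty. Counts are realised as dated events with outcome-specific
#' subtypes; with probability `duplicate_event_prob` an event is duplicated
#' same-day/same-type to exercise deduplication. Fully deterministic under
#' `config$seed`.
#'
#' @param config a [sim_config()] object.
#' @return list of class `mmi_dataset`: `children`, `mothers`,
#'   `clinical_events`, `use_events`, `codelist`, `tariffs`, `cpi`,
#'   `population`, and `truth` (the config, planted onsets, true exposure
#'   segments and realised per-cell true rates).
#' @export
simulate_cohort <- function(config) {
  cfg <- if (inherits(config, "mmi_sim_config")) config else do.call(sim_config, config)
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_mothers
  codelist <- default_codelist()

  # --- mothers and their practices ------------------------------------------
  reg_start <- cfg$study_start - (TWO_YEARS_DAYS +
    floor(runif(n) * (15 * DAYS_PER_YEAR)))
  early_end <- runif(n) < 0.08
  reg_end <- as.Date(ifelse(
    early_end,
    runif_date(rep(cfg$study_start + 365L, n), rep(cfg$study_end, n)),
    cfg$study_end + 365L + floor(runif(n) * (4 * DAYS_PER_YEAR))
  ), origin = "1970-01-01")
  death <- rep(as.Date(NA), n)
  dies <- runif(n) < 0.005
  death[dies] <- runif_date(rep(cfg$study_start, sum(dies)),
                            rep(cfg$study_end, sum(dies)))
  reg_end <- pmin_date(reg_end, death)
  p_uts <- cfg$study_start - floor(runif(n, -730, 4000))
  p_colend <- as.Date(ifelse(
    runif(n) < 0.95,
    cfg$study_end + floor(runif(n) * (3 * DAYS_PER_YEAR)),
    runif_date(rep(cfg$study_start + 365L, n), rep(cfg$study_end, n))
  ), origin = "1970-01-01")
  mothers <- data.table(
    mother_id = sprintf("M%06d", seq_len(n)),
    registration_start = reg_start, registration_end = reg_end,
    death_date = death, practice_uts_date = p_uts,
    practice_collection_end = p_colend
  )
  frailty_m <- rgamma_frailty(n, cfg$overdispersion)

  # --- planted illness onsets and raw clinical events -----------------------
  mmi <- simulate_mmi_events(mothers, cfg, codelist)

  # --- children --------------------------------------------------------------
  k <- pmin(rpois(n, cfg$mean_children_per_mother - 1) + 1L, 6L)
  mi <- rep(seq_len(n), k)
  nc <- length(mi)
  birth <- runif_date(rep(cfg$birth_start, nc), rep(cfg$birth_end, nc))
  c_reg_start <- birth + floor(runif(nc) * 31)
  dropout_years <- if (cfg$dropout_hazard > 0) {
    rexp(nc, rate = cfg$dropout_hazard)
  } else {
    rep(Inf, nc)
  }
  c_reg_end <- pmin_date(
    c_reg_start + ceiling(pmin(dropout_years, 25) * DAYS_PER_YEAR),
    add_years(birth, 19L)
  )
  c_death <- rep(as.Date(NA), nc)
  c_dies <- runif(nc) < 0.003
  c_death[c_dies] <- birth[c_dies] +
    ceiling(runif(sum(c_dies)) * 10 * DAYS_PER_YEAR)
  children <- data.table(
    child_id = sprintf("C%07d", seq_len(nc)),
    mother_id = mothers$mother_id[mi],
    birth_date = birth, death_date = c_death,
    sex = sample(c("F", "M"), nc, replace = TRUE, prob = c(0.487, 0.513)),
    imd_quintile = sample(1:5, nc, replace = TRUE),
    registration_start = c_reg_start, registration_end = c_reg_end,
    practice_uts_date = mothers$practice_uts_date[mi],
    practice_collection_end = mothers$practice_collection_end[mi],
    hes_linked = runif(nc) < cfg$hes_linked_prob
  )
  frailty_c <- frailty_m[mi] * rgamma_frailty(nc, cfg$child_overdispersion)

  # --- true person-time and exposure ----------------------------------------
  ch_fu <- follow_up_interval(children, mothers, cfg$study_start,
                              cfg$study_end)
  seg <- as.data.table(split_age_bands(ch_fu))
  # planting only needs the any-MMI flag; analyses derive the full category
  # flags from the raw events downstream
  seg <- as.data.table(assign_exposure(seg, mmi$truth_det, mode = "main",
                                       categories = exposure_categories()["any"]))
  seg[, frailty := frailty_c[match(child_id, children$child_id)]]

  # --- planted counts ---------------------------------------------------------
  plant <- build_plant_table(cfg)
  S <- nrow(seg)
  counts <- list()
  period_mult <- exp(cfg$period_effect_per_year * (seg$period - 2007L))
  cells <- unique(plant[, .(outcome, subcat)])
  for (i in seq_len(nrow(cells))) {
    o <- cells$outcome[i]
    sc <- cells$subcat[i]
    pr <- plant[outcome == o & subcat == sc]
    base <- pr$base_rate[match(seg$age_band, pr$age_band)]
    rr <- pr$rate_ratio[match(seg$age_band, pr$age_band)]
    mu <- base * ifelse(seg$exposed_any, rr, 1) * period_mult *
      seg$person_years * seg$frailty
    counts[[i]] <- data.table(seg_idx = seq_len(S), outcome = o, subcat = sc,
                              count = rpois(S, mu))
  }
  counts <- rbindlist(counts)

  # --- realise events ---------------------------------------------------------
  pos <- counts[count > 0L]
  idx <- rep(pos$seg_idx, pos$count)
  ne <- length(idx)
  e_outcome <- rep(pos$outcome, pos$count)
  e_subcat <- rep(pos$subcat, pos$count)
  e_date <- as.Date(
    as.numeric(seg$seg_start[idx]) + floor(runif(ne) * seg$seg_days[idx]),
    origin = "1970-01-01"
  )
  e_cons <- rep(NA_character_, ne)
  e_staff <- rep(NA_character_, ne)
  e_epi <- rep(NA_character_, ne)
  e_los <- rep(NA_integer_, ne)
  e_drug <- rep(NA_character_, ne)
  pc_i <- which(e_outcome == "primary_care")
  if (length(pc_i)) {
    e_cons[pc_i] <- sample(c("face-to-face", "telephone", "home-visit"),
                           length(pc_i), replace = TRUE,
                           prob = c(0.7, 0.2, 0.1))
    e_staff[pc_i] <- sample(c("doctor", "nurse", "health-visitor", "other"),
                            length(pc_i), replace = TRUE,
                            prob = c(0.6, 0.3, 0.05, 0.05))
  }
  in_i <- which(e_outcome == "inpatient")
  if (length(in_i)) {
    e_epi[in_i] <- sample(
      c("day-case", "regular-day-night", "elective", "non-elective"),
      length(in_i), replace = TRUE, prob = c(0.3, 0.1, 0.2, 0.4)
    )
    e_los[in_i] <- 0L
    los_dep <- in_i[e_epi[in_i] %in% c("elective", "non-elective")]
    e_los[los_dep] <- rpois(length(los_dep), 2)
  }
  rx_i <- which(e_outcome == "prescription")
  dc <- default_drug_codes()
  if (length(rx_i)) {
    if (is.null(cfg$prescription_categories)) {
      e_drug[rx_i] <- sample(dc$drug_code, length(rx_i), replace = TRUE)
    } else {
      for (catg in unique(e_subcat[rx_i])) {
        ri <- rx_i[e_subcat[rx_i] == catg]
        cand <- dc[dc$drug_category == catg, ]
        e_drug[ri] <- sample(cand$drug_code, length(ri), replace = TRUE,
                             prob = cand$share)
      }
    }
  }
  # redraw chance same-day same-type collisions so realised deduplicated
  # counts match the planted counts (deduplication is exercised by the
  # planted duplicates below, not by accidents of date sampling)
  if (ne > 0L) {
    oid <- chmatch(e_outcome, unique(e_outcome))
    kid <- event_dedup_key(
      data.frame(outcome = e_outcome, consultation_type = e_cons,
                 staff = e_staff, drug_code = e_drug,
                 stringsAsFactors = FALSE),
      "subtype"
    )
    for (pass in 1:5) {
      dup <- duplicated(data.table(idx, e_date, oid, kid))
      if (!any(dup)) break
      redraw <- which(dup & seg$seg_days[idx] > 1)
      if (!length(redraw)) break
      e_date[redraw] <- as.Date(
        as.numeric(seg$seg_start[idx[redraw]]) +
          floor(runif(length(redraw)) * seg$seg_days[idx[redraw]]),
        origin = "1970-01-01"
      )
    }
  }
  ev <- setDT(list(
    child_id = seg$child_id[idx], date = e_date, outcome = e_outcome,
    consultation_type = e_cons, staff = e_staff, episode_type = e_epi,
    length_of_stay = e_los, drug_code = e_drug,
    drug_category = dc$drug_category[match(e_drug, dc$drug_code)]
  ))

  # same-day same-type duplicates, to exercise deduplication downstream
  extra <- list()
  if (cfg$duplicate_event_prob > 0 && ne > 0L) {
    dup <- which(runif(ne) < cfg$duplicate_event_prob)
    extra$dup <- ev[dup]
  }

  # a little pre-follow-up noise inside registration, dropped by the counter
  ch_dt <- as.data.table(ch_fu)
  pre <- ch_dt[!is.na(fu_start) &
                 as.numeric(fu_start - registration_start) > 30]
  if (nrow(pre)) {
    pre <- pre[runif(.N) < 0.1]
  }
  if (nrow(pre)) {
    extra$noise <- data.table(
      child_id = pre$child_id,
      date = runif_date(pre$registration_start, pre$fu_start - 1L),
      outcome = "primary_care",
      consultation_type = "face-to-face", staff = "doctor",
      episode_type = NA_character_, length_of_stay = NA_integer_,
      drug_code = NA_character_, drug_category = NA_character_
    )
  }
  if (length(extra)) {
    ev <- rbindlist(c(list(ev), extra), use.names = TRUE)
  }

  # --- realised per-cell true rates ------------------------------------------
  counts[, py := seg$person_years[seg_idx]]
  counts[, exposed := seg$exposed_any[seg_idx]]
  tr <- counts[, .(events = sum(count), person_years = sum(py)),
               by = .(outcome, age_band = seg$age_band[seg_idx], exposed)]
  tr_tot <- counts[, .(events = sum(count), person_years = sum(py[outcome == outcome[1L]])),
                   by = .(age_band = seg$age_band[seg_idx], exposed)]
  tr_tot[, outcome := "total"]
  true_rates <- rbind(tr, tr_tot, use.names = TRUE)
  true_rates[, rate := events / person_years]

  structure(list(
    children = setDF(children), mothers = setDF(mothers),
    clinical_events = setDF(mmi$clinical_events),
    use_events = setDF(ev),
    codelist = codelist,
    tariffs = default_tariffs(),
    cpi = default_cpi(),
    population = default_population(),
    truth = list(config = cfg, onsets = setDF(mmi$onsets),
                 determinations = setDF(mmi$truth_det),
                 segments = setDF(seg), true_rates = setDF(true_rates))
  ), class = "mmi_dataset")
}
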