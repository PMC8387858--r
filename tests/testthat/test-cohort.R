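# Follow-up construction, eligibility rules, age-band splitting and exposure
# windows.

simple_child <- function(birth, reg_start = birth, reg_end = "2030-01-01",
                         uts = "2005-01-01", colend = "2025-01-01",
                         hes = TRUE, death = NA) {
  data.frame(
    child_id = "c1", mother_id = "m1", birth_date = as.Date(birth),
    death_date = as.Date(death), sex = "F", imd_quintile = 2L,
    registration_start = as.Date(reg_start),
    registration_end = as.Date(reg_end),
    practice_uts_date = as.Date(uts),
    practice_collection_end = as.Date(colend),
    hes_linked = hes, stringsAsFactors = FALSE
  )
}

simple_mother <- function(reg_start = "1990-01-01", reg_end = "2030-01-01",
                          death = NA, uts = "2005-01-01") {
  data.frame(
    mother_id = "m1", registration_start = as.Date(reg_start),
    registration_end = as.Date(reg_end), death_date = as.Date(death),
    practice_uts_date = as.Date(uts),
    practice_collection_end = as.Date("2025-01-01"), stringsAsFactors = FALSE
  )
}

test_that("follow-up is the latest start to the earliest end", {
  ch <- follow_up_interval(simple_child("2010-01-01"), simple_mother())
  expect_equal(ch$fu_start, as.Date("2010-01-01"))
  # 18th birthday is after the study end, so the study end binds
  expect_equal(ch$fu_end, as.Date("2017-07-31"))
  # an early registration end binds instead
  ch <- follow_up_interval(simple_child("2010-01-01", reg_end = "2013-05-01"),
                           simple_mother())
  expect_equal(ch$fu_end, as.Date("2013-05-01"))
  # the mother's death binds when earliest
  ch <- follow_up_interval(simple_child("2010-01-01"),
                           simple_mother(death = "2012-02-03"))
  expect_equal(ch$fu_end, as.Date("2012-02-03"))
})

test_that("registration ending before the study start yields no follow-up", {
  ch <- follow_up_interval(
    simple_child("1995-03-01", reg_end = "2001-01-01"), simple_mother()
  )
  expect_true(is.na(ch$fu_start))
  expect_true(is.na(ch$fu_days))
})

test_that("follow-up bounds equal a brute-force candidate enumeration", {
  children <- random_children(1000, seed = 11)
  mothers <- random_mothers_for(children)
  out <- follow_up_interval(children, mothers)
  study_start <- as.Date("2007-04-01")
  study_end <- as.Date("2017-07-31")
  for (i in sample.int(1000, 200)) {
    starts <- c(children$birth_date[i], children$practice_uts_date[i],
                children$registration_start[i], study_start)
    ends <- c(children$registration_end[i],
              add_years(children$birth_date[i], 18),
              children$death_date[i], mothers$death_date[i],
              children$practice_collection_end[i], study_end)
    s <- max(starts, na.rm = TRUE)
    e <- min(ends, na.rm = TRUE)
    if (e <= s) {
      expect_true(is.na(out$fu_start[i]))
    } else {
      expect_equal(out$fu_start[i], s)
      expect_equal(out$fu_end[i], e)
    }
  }
})

test_that("eligibility rules exclude planted violations with an exact tally", {
  base_child <- simple_child("2010-01-01")
  base_mother <- simple_mother()
  children <- do.call(rbind, lapply(1:5, function(i) base_child))
  children$child_id <- sprintf("c%d", 1:5)
  children$mother_id <- sprintf("m%d", 1:5)
  mothers <- do.call(rbind, lapply(1:5, function(i) base_mother))
  mothers$mother_id <- sprintf("m%d", 1:5)
  children$hes_linked[2] <- FALSE                     # linkage violation
  children$registration_end[3] <- as.Date("2010-01-20")  # 19 days < 30.5
  mothers$practice_uts_date[4] <- as.Date("2012-01-01")  # not UTS at start
  mothers$registration_end[5] <- as.Date("2011-01-01")   # < 2y after start
  res <- apply_eligibility(children, mothers)
  expect_equal(res$n_eligible, 1L)
  expect_equal(res$children$child_id, "c1")
  tally <- setNames(res$exclusions$n, res$exclusions$reason)
  expect_equal(unname(tally[c("no_hes_linkage", "follow_up_lt_30.5_days",
                              "mother_not_uts_at_start",
                              "mother_lt_2y_data")]), rep(1L, 4))
})

test_that("a mother registered [start-3y, start+1y] fails the 2-year-after rule", {
  ch <- simple_child("2010-01-01")
  mo <- simple_mother(reg_start = "2007-01-01", reg_end = "2011-01-01")
  res <- apply_eligibility(ch, mo)
  expect_equal(res$n_eligible, 0L)
  expect_equal(res$exclusions$n[res$exclusions$reason == "mother_lt_2y_data"], 1L)
})

test_that("children with unmatched mothers or missing birth dates get their own reason codes", {
  ch <- simple_child("2010-01-01")
  ch$mother_id <- "nope"
  res <- apply_eligibility(ch, simple_mother())
  expect_equal(res$exclusions$n[res$exclusions$reason == "no_mother_record"], 1L)
  ch2 <- simple_child("2010-01-01")
  ch2$birth_date <- as.Date(NA)
  res2 <- apply_eligibility(ch2, simple_mother())
  expect_equal(res2$exclusions$n[res2$exclusions$reason == "missing_birth_date"], 1L)
  expect_equal(res2$n_eligible, 0L)
})

test_that("full 0-18 follow-up splits into five bands totalling 18 years", {
  ch <- simple_child("1994-06-15", uts = "1990-01-01", colend = "2030-01-01")
  fu <- follow_up_interval(ch, simple_mother(),
                           study_start = as.Date("1990-01-01"),
                           study_end = as.Date("2020-01-01"))
  seg <- split_age_bands(fu)
  expect_equal(nrow(seg), 5L)
  expect_equal(seg$age_band, age_band_levels())
  expect_equal(sum(seg$person_years), 18, tolerance = 0.01 / 18)
})

test_that("a half-year straddle splits at the first birthday", {
  ch <- simple_child("2010-01-01", reg_start = "2010-07-02",
                     reg_end = "2011-07-02")
  fu <- follow_up_interval(ch, simple_mother())
  seg <- split_age_bands(fu)
  expect_equal(seg$age_band, c("<1", "1-4"))
  expect_equal(seg$seg_days, c(183, 182))
  expect_equal(seg$seg_start[2], as.Date("2011-01-01"))
})

test_that("person-time is conserved and confined to ages 0-18 on random children", {
  children <- random_children(2000, seed = 23)
  mothers <- random_mothers_for(children)
  fu <- follow_up_interval(children, mothers)
  seg <- split_age_bands(fu)
  py <- tapply(seg$person_years, seg$child_id, sum)
  fu_ok <- fu[!is.na(fu$fu_days), ]
  expect_equal(
    as.vector(py[fu_ok$child_id]), fu_ok$fu_days / 365.25,
    tolerance = 1e-9
  )
  sdt <- merge(seg, fu_ok[, c("child_id", "birth_date")], by = "child_id")
  age_start <- as.numeric(sdt$seg_start - sdt$birth_date) / 365.25
  age_end <- as.numeric(sdt$seg_end - sdt$birth_date) / 365.25
  expect_true(all(age_start >= 0))
  expect_true(all(age_end <= 18.01))
  # segments stay inside their band's age interval (calendrical bounds)
  bands <- age_bands()
  lower <- bands$lower[match(sdt$age_band, bands$age_band)]
  upper <- bands$upper[match(sdt$age_band, bands$age_band)]
  expect_true(all(sdt$seg_start >= add_years(sdt$birth_date, lower)))
  expect_true(all(sdt$seg_end <= add_years(sdt$birth_date, upper)))
})

test_that("exposure windows: main covers the band, sensitivity stops at band start", {
  seg <- make_segments("c1", "m1", "2010-01-01", "2012-01-01")
  det <- function(d) data.frame(mother_id = "m1", illness = "depression",
                                case_date = as.Date(d), pathway = "diagnosis",
                                stringsAsFactors = FALSE)
  # one day before the band start: exposed in both modes
  expect_true(assign_exposure(seg, det("2009-12-31"), "main")$exposed_any)
  expect_true(assign_exposure(seg, det("2009-12-31"), "sensitivity")$exposed_any)
  # mid-band: main only
  expect_true(assign_exposure(seg, det("2011-06-01"), "main")$exposed_any)
  expect_false(assign_exposure(seg, det("2011-06-01"), "sensitivity")$exposed_any)
  # more than 2 years before the band start: neither
  expect_false(assign_exposure(seg, det("2007-12-31"), "main")$exposed_any)
  # exactly 730 days before: both (closed window start)
  expect_true(assign_exposure(seg, det("2008-01-02"), "main")$exposed_any)
})

test_that("exposure flags equal a brute-force window scan on random cohorts", {
  set.seed(31)
  seg <- make_segments(
    sprintf("c%03d", 1:150),
    mother_id = sprintf("m%03d", sample.int(60, 150, replace = TRUE)),
    seg_start = as.Date("2008-01-01") + sample.int(2500, 150, TRUE),
    seg_end = as.Date("2015-01-01") + sample.int(800, 150, TRUE)
  )
  det <- data.frame(
    mother_id = sprintf("m%03d", sample.int(60, 300, replace = TRUE)),
    illness = sample(names(default_mmi_prevalence()), 300, replace = TRUE),
    case_date = as.Date("2006-01-01") + sample.int(4000, 300, TRUE),
    pathway = "diagnosis", stringsAsFactors = FALSE
  )
  cats <- exposure_categories()
  for (mode in c("main", "sensitivity")) {
    out <- assign_exposure(seg, det, mode)
    for (i in seq_len(nrow(seg))) {
      lo <- seg$band_start_date[i] - 730
      hi <- if (mode == "main") seg$seg_end[i] else seg$band_start_date[i] - 1
      for (nm in names(cats)) {
        brute <- any(det$mother_id == seg$mother_id[i] &
                       det$illness %in% cats[[nm]] &
                       det$case_date >= lo & det$case_date <= hi)
        expect_identical(out[[paste0("exposed_", nm)]][i], brute)
      }
    }
  }
})

test_that("sensitivity-mode exposure is a subset of main-mode exposure", {
  ds <- simulate_cohort(sim_config(n_mothers = 300, seed = 99))
  det <- classify_cases(ds$clinical_events, ds$codelist)
  elig <- apply_eligibility(ds$children, ds$mothers)
  seg <- split_age_bands(elig$children)
  main <- assign_exposure(seg, det, "main")
  sens <- assign_exposure(seg, det, "sensitivity")
  for (nm in names(exposure_categories())) {
    cn <- paste0("exposed_", nm)
    expect_true(all(!sens[[cn]] | main[[cn]]))
  }
})
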