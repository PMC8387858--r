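# Event counting: same-day same-type deduplication, segment assignment,
# zero preservation and integer conservation.

test_that("same-day contacts of the same type count once, different types count separately", {
  seg <- make_segments("c1", "m1", "2010-01-01", "2011-01-01")
  f2f <- make_event("c1", "2010-05-01", "primary_care",
                    consultation_type = "face-to-face", staff = "doctor")
  tel <- make_event("c1", "2010-05-01", "primary_care",
                    consultation_type = "telephone", staff = "doctor")
  res <- count_events(rbind(f2f, f2f), seg)
  expect_equal(res$count[res$outcome == "primary_care"], 1L)
  res <- count_events(rbind(f2f, tel), seg)
  expect_equal(res$count[res$outcome == "primary_care"], 2L)
  # same-day prescriptions deduplicate on the drug code
  rx1 <- make_event("c1", "2010-05-01", "prescription", drug_code = "AAA")
  rx2 <- make_event("c1", "2010-05-01", "prescription", drug_code = "BBB")
  res <- count_events(rbind(rx1, rx1, rx2), seg)
  expect_equal(res$count[res$outcome == "prescription"], 2L)
  # at the outcome dedup level the whole day collapses
  res <- count_events(rbind(f2f, tel), seg, dedup_level = "outcome")
  expect_equal(res$count[res$outcome == "primary_care"], 1L)
})

test_that("no events still yields zero-count records for every segment and outcome", {
  seg <- make_segments(c("c1", "c2"), c("m1", "m2"),
                       c("2010-01-01", "2011-01-01"),
                       c("2011-01-01", "2012-01-01"))
  res <- count_events(make_event(character(), as.Date(character()), character()), seg)
  expect_equal(nrow(res), 2L * 7L)  # six outcomes + total
  expect_true(all(res$count == 0L))
})

test_that("events are assigned to the containing segment; outside events are dropped and tallied", {
  seg <- rbind(make_segments("c1", "m1", "2010-01-01", "2011-01-01",
                             age_band = "<1"),
               make_segments("c1", "m1", "2011-01-01", "2012-01-01",
                             age_band = "1-4"))
  ev <- rbind(
    make_event("c1", "2010-12-31", "emergency"),
    make_event("c1", "2011-01-01", "emergency"),  # band boundary: older band
    make_event("c1", "2012-01-01", "emergency"),  # end date: outside (half-open)
    make_event("c2", "2011-06-01", "emergency")   # unknown child: outside
  )
  res <- count_events(ev, seg)
  em <- res[res$outcome == "emergency", ]
  expect_equal(em$count[em$age_band == "<1"], 1L)
  expect_equal(em$count[em$age_band == "1-4"], 1L)
  expect_equal(attr(res, "n_dropped"), 2L)
})

test_that("per-outcome counts sum exactly to the total record", {
  set.seed(41)
  seg <- make_segments(sprintf("c%02d", 1:20), sprintf("m%02d", 1:20),
                       rep("2010-01-01", 20), rep("2012-01-01", 20))
  n <- 500
  ev <- make_event(
    sample(sprintf("c%02d", 1:20), n, replace = TRUE),
    as.Date("2010-01-01") + sample(0:729, n, replace = TRUE),
    sample(c("primary_care", "prescription", "referral", "outpatient",
             "inpatient", "emergency"), n, replace = TRUE)
  )
  ev$drug_code[ev$outcome == "prescription"] <- "X"
  res <- count_events(ev, seg)
  tot <- tapply(res$count[res$outcome != "total"],
                res$child_id[res$outcome != "total"], sum)
  tot_rec <- res[res$outcome == "total", ]
  expect_equal(as.vector(tot[tot_rec$child_id]), tot_rec$count)
})

test_that("counting agrees with a brute-force group-by oracle on random inputs", {
  set.seed(53)
  for (rep in 1:3) {
    seg <- rbind(
      make_segments(sprintf("c%02d", 1:10), sprintf("m%02d", 1:10),
                    rep("2010-01-01", 10), rep("2011-01-01", 10),
                    age_band = "<1"),
      make_segments(sprintf("c%02d", 1:10), sprintf("m%02d", 1:10),
                    rep("2011-01-01", 10), rep("2013-06-01", 10),
                    age_band = "1-4")
    )
    n <- 400
    ev <- make_event(
      sample(sprintf("c%02d", 1:12), n, replace = TRUE),
      as.Date("2009-06-01") + sample(0:1800, n, replace = TRUE),
      sample(c("primary_care", "emergency"), n, replace = TRUE),
      consultation_type = sample(c("face-to-face", "telephone"), n, TRUE),
      staff = sample(c("doctor", "nurse"), n, TRUE)
    )
    ev$consultation_type[ev$outcome != "primary_care"] <- NA
    ev$staff[ev$outcome != "primary_care"] <- NA
    res <- count_events(ev, seg)
    # oracle: dedup by explicit key, then per-segment interval scan
    key <- paste(ev$child_id, ev$date, ev$outcome,
                 ifelse(ev$outcome == "primary_care",
                        paste(ev$consultation_type, ev$staff), ""))
    dd <- ev[!duplicated(key), ]
    for (i in seq_len(nrow(seg))) {
      inseg <- dd$child_id == seg$child_id[i] &
        dd$date >= seg$seg_start[i] & dd$date < seg$seg_end[i]
      for (o in c("primary_care", "emergency")) {
        got <- res$count[res$child_id == seg$child_id[i] &
                           res$age_band == seg$age_band[i] &
                           res$outcome == o]
        expect_equal(got, sum(inseg & dd$outcome == o))
      }
    }
  }
})

test_that("deduplicated counts never exceed raw counts, equal without duplicates", {
  ds <- simulate_cohort(sim_config(n_mothers = 150, seed = 77,
                                   duplicate_event_prob = 0.2))
  seg <- ds$truth$segments
  raw <- count_events(unique(ds$use_events), seg)  # unique() drops exact copies
  res <- count_events(ds$use_events, seg)
  expect_identical(res$count, raw$count)
  expect_true(sum(res$count[res$outcome != "total"]) <= nrow(ds$use_events))
  ds0 <- simulate_cohort(sim_config(n_mothers = 150, seed = 77,
                                    duplicate_event_prob = 0))
  # with no planted duplicates, dedup only removes chance collisions
  res0 <- count_events(ds0$use_events, ds0$truth$segments)
  dropped0 <- attr(res0, "n_dropped")
  expect_equal(sum(res0$count[res0$outcome != "total"]) + dropped0,
               nrow(ds0$use_events))
})

test_that("drug-category tabulation recovers a planted category rate ratio", {
  ds <- simulate_cohort(sim_config(n_mothers = 4000, seed = 5))
  det <- classify_cases(ds$clinical_events, ds$codelist)
  elig <- apply_eligibility(ds$children, ds$mothers)
  seg <- assign_exposure(split_age_bands(elig$children), det)
  tab <- tabulate_by_drug_category(ds$use_events, seg)
  expect_true(all(default_prescription_categories()$category %in%
                    tab$drug_category))
  planted <- default_prescription_categories()
  got <- tab$rate_ratio[match(planted$category, tab$drug_category)]
  # Monte-Carlo agreement: planted ratios span 1.15-1.77
  expect_equal(got, planted$rate_ratio, tolerance = 0.12)
  expect_true(cor(got, planted$rate_ratio) > 0.9)
})

test_that("empty and uncategorised prescriptions are handled", {
  seg <- make_segments("c1", "m1", "2010-01-01", "2011-01-01",
                       exposed_any = TRUE)
  seg <- rbind(seg, make_segments("c2", "m2", "2010-01-01", "2011-01-01"))
  expect_equal(nrow(tabulate_by_drug_category(
    make_event(character(), as.Date(character()), character()), seg)), 0L)
  ev <- make_event("c1", "2010-05-01", "prescription", drug_code = "Z")
  tab <- tabulate_by_drug_category(ev, seg)
  expect_equal(tab$drug_category, "uncategorised")
})
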