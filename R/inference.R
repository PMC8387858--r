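# Rate ratio and rate difference estimation.
#
# Counts per (child, age band) segment are modelled with NB2 negative
# binomial regression, log link, offset log person-years, covariates period
# (categorical year the band started) and age band, and an age-band x
# exposure interaction for band-specific contrasts. Standard errors use the
# Huber-White sandwich estimator clustered on the mother. The pooled
# ("all ages") effect refits without the interaction term.

#' Crude two-group rates
#'
#' Arm rate = total events / total person-years; the crude rate difference is
#' exposed minus unexposed, the crude ratio exposed over unexposed.
#'
#' @param records count (or cost) records with `count` (or `cost`),
#'   `person_years` and an `exposed_<category>` flag.
#' @param category exposure category name.
#' @param value_col column holding the per-segment numerator (default
#'   `"count"`; use `"cost"` for cost rates).
#' @return one-row data.frame: `rate_exposed`, `rate_unexposed`,
#'   `rate_ratio`, `rate_difference`, person-years per arm.
#' @export
two_group_rates <- function(records, category = "any", value_col = "count") {
  d <- as.data.table(records)
  flag <- paste0("exposed_", category)
  stopifnot(flag %in% names(d), value_col %in% names(d))
  e <- d[[flag]]
  py_e <- sum(d$person_years[e])
  py_u <- sum(d$person_years[!e])
  if (py_e <= 0 || py_u <= 0) {
    warning("empty exposure arm: rates undefined")
    return(data.frame(rate_exposed = NA_real_, rate_unexposed = NA_real_,
                      rate_ratio = NA_real_, rate_difference = NA_real_,
                      py_exposed = py_e, py_unexposed = py_u))
  }
  r_e <- sum(d[[value_col]][e]) / py_e
  r_u <- sum(d[[value_col]][!e]) / py_u
  data.frame(rate_exposed = r_e, rate_unexposed = r_u,
             rate_ratio = r_e / r_u, rate_difference = r_e - r_u,
             py_exposed = py_e, py_unexposed = py_u)
}

# negative binomial fit with the dispersion handling requested:
#   "estimate"  ML scalar dispersion (NB2) via glm.nb
#   0           Poisson limit
#   alpha > 0   fixed dispersion, theta = 1/alpha
fit_nb <- function(formula, data, dispersion = "estimate") {
  if (identical(dispersion, "estimate")) {
    fit <- withCallingHandlers(
      tryCatch(
        MASS::glm.nb(formula, data = data),
        error = function(e) {
          # restart from Poisson estimates, then fail loudly
          start <- tryCatch(
            coef(glm(formula, data = data, family = poisson())),
            error = function(e2) NULL
          )
          if (is.null(start)) stop(e)
          tryCatch(
            MASS::glm.nb(formula, data = data, start = start),
            error = function(e3) {
              stop("negative binomial fit failed to converge: ",
                   conditionMessage(e3), call. = FALSE)
            }
          )
        }
      ),
      warning = function(w) {
        # theta walking to +Inf on equidispersed data is benign (Poisson limit)
        if (grepl("iteration limit|theta", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    return(fit)
  }
  stopifnot(is.numeric(dispersion), dispersion >= 0)
  if (dispersion == 0) {
    glm(formula, data = data, family = poisson())
  } else {
    glm(formula, data = data,
        family = MASS::negative.binomial(theta = 1 / dispersion))
  }
}

# linear-combination Wald interval on the log scale
lincom <- function(beta, V, L, level = 0.95) {
  est <- sum(L * beta)
  se <- sqrt(drop(t(L) %*% V %*% L))
  z <- qnorm(1 - (1 - level) / 2)
  c(est = est, lo = est - z * se, hi = est + z * se, se = se)
}

# person-year-weighted marginal standardization: average model-predicted rate
# with exposure forced to 1 vs 0, over the observed covariate rows `idx`
marginal_rates <- function(fit, data, exposed_col, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(nrow(data))
  d1 <- data[idx, ]
  tt <- delete.response(terms(fit))
  d0 <- d1
  d1[[exposed_col]] <- 1L
  d0[[exposed_col]] <- 0L
  X1 <- model.matrix(tt, d1)
  X0 <- model.matrix(tt, d0)
  b <- coef(fit)
  keep <- !is.na(b)
  r1 <- exp(drop(X1[, keep, drop = FALSE] %*% b[keep]))
  r0 <- exp(drop(X0[, keep, drop = FALSE] %*% b[keep]))
  w <- d1$person_years
  c(exposed = weighted.mean(r1, w), unexposed = weighted.mean(r0, w))
}

#' Fit the rate model for one outcome and exposure category
#'
#' Fits the negative binomial rate model and returns one effect estimate per
#' age band (from the interaction model) plus a pooled `"all"` row (model
#' without the interaction). Rate ratios are exponentiated exposure contrasts
#' with Wald intervals from the mother-clustered sandwich variance. Rate
#' differences are obtained by person-year-weighted marginal standardization
#' over the observed covariate rows; their intervals, when requested via
#' `rd_boot`, come from a cluster bootstrap of the crude per-band differences
#' (mothers resampled with replacement, children travelling with their
#' mother).
#'
#' @param records count records for a single outcome (see [count_events()]);
#'   use `value_col = "cost"` with cost records from [cost_rates()].
#' @param category exposure category name (flag column `exposed_<category>`).
#' @param adjust_imd adjust for IMD quintile (categorical).
#' @param dispersion `"estimate"` (NB2, ML scalar), `0` (Poisson limit) or a
#'   fixed positive NB2 dispersion alpha.
#' @param include_period include the categorical period covariate.
#' @param include_age_band include the age-band covariate in the pooled
#'   model (the interaction model always has it); turn off together with
#'   `include_period` for a pure two-group fit.
#' @param by_band fit the interaction model for band-specific estimates.
#' @param pooled fit the no-interaction model for the `"all"` row.
#' @param rd_boot number of cluster-bootstrap resamples for rate-difference
#'   intervals (0 = skip).
#' @param value_col numerator column, `"count"` (integer counts; default).
#' @param level confidence level.
#' @return data.frame, one row per age band (plus `"all"`): crude arm rates,
#'   model rate ratio with CI, marginal-standardized and crude rate
#'   differences (with bootstrap CI when `rd_boot > 0`), observation and
#'   cluster counts, and a `degenerate` flag for cells with an all-zero arm.
#' @export
fit_cell <- function(records, category = "any", adjust_imd = FALSE,
                     dispersion = "estimate", include_period = TRUE,
                     include_age_band = TRUE, by_band = TRUE, pooled = TRUE,
                     rd_boot = 0L, value_col = "count", level = 0.95) {
  d <- as.data.table(records)
  flag <- paste0("exposed_", category)
  stopifnot(flag %in% names(d))
  if ("outcome" %in% names(d) && length(unique(d$outcome)) > 1L) {
    stop("records span several outcomes; filter to one before fitting",
         call. = FALSE)
  }
  d <- d[person_years > 0]
  d[, exposed := as.integer(get(flag))]
  d[, count := get(value_col)]
  d[, age_band := factor(age_band, levels = age_band_levels())]
  d[, age_band := droplevels(age_band)]
  d[, period := factor(period)]
  if (adjust_imd) d[, imd_quintile := factor(imd_quintile)]
  d[, mother_id := as.character(mother_id)]

  for (arm in 0:1) {
    if (length(unique(d$mother_id[d$exposed == arm])) < 2L) {
      stop("fewer than 2 mother clusters in an exposure arm", call. = FALSE)
    }
  }

  bands <- levels(d$age_band)
  covars <- c(
    if (include_age_band && length(bands) > 1L) "age_band",
    if (include_period && length(unique(d$period)) > 1L) "period",
    if (adjust_imd) "imd_quintile"
  )
  z <- qnorm(1 - (1 - level) / 2)

  degenerate_arm <- function(dd) {
    sum(dd$count[dd$exposed == 1L]) == 0 || sum(dd$count[dd$exposed == 0L]) == 0
  }

  rows <- list()

  fit_one <- function(dd, band_label, interaction) {
    crude <- two_group_rates(dd, category, value_col)
    deg <- degenerate_arm(dd)
    row <- data.frame(
      age_band = band_label, category = category,
      rate_exposed = crude$rate_exposed, rate_unexposed = crude$rate_unexposed,
      rate_ratio = NA_real_, rr_lo = NA_real_, rr_hi = NA_real_,
      rate_difference = NA_real_, rd_crude = crude$rate_difference,
      rd_lo = NA_real_, rd_hi = NA_real_,
      model_rate_exposed = NA_real_, model_rate_unexposed = NA_real_,
      n_obs = nrow(dd), n_mothers = length(unique(dd$mother_id)),
      degenerate = deg, stringsAsFactors = FALSE
    )
    if (deg) return(list(row = row, fit = NULL))

    trm <- if (interaction) {
      c("exposed * age_band", setdiff(covars, "age_band"))
    } else {
      c("exposed", covars)
    }
    fml <- as.formula(paste("count ~", paste(trm, collapse = " + "),
                            "+ offset(log(person_years))"))
    fit <- fit_nb(fml, dd, dispersion)
    V <- sandwich::vcovCL(fit, cluster = dd$mother_id)
    b <- coef(fit)
    b <- b[!is.na(b)]  # drop aliased columns; V is already non-aliased

    if (interaction) {
      sub_rows <- lapply(levels(dd$age_band), function(bnd) {
        L <- as.numeric(names(b) == "exposed") +
          as.numeric(names(b) == paste0("exposed:age_band", bnd))
        ci <- lincom(b, V, L, level)
        idx <- which(dd$age_band == bnd)
        mr <- marginal_rates(fit, dd, "exposed", idx)
        crude_b <- two_group_rates(dd[idx], category, value_col)
        data.frame(
          age_band = bnd, category = category,
          rate_exposed = crude_b$rate_exposed,
          rate_unexposed = crude_b$rate_unexposed,
          rate_ratio = exp(ci[["est"]]), rr_lo = exp(ci[["lo"]]),
          rr_hi = exp(ci[["hi"]]),
          rate_difference = mr[["exposed"]] - mr[["unexposed"]],
          rd_crude = crude_b$rate_difference,
          rd_lo = NA_real_, rd_hi = NA_real_,
          model_rate_exposed = mr[["exposed"]],
          model_rate_unexposed = mr[["unexposed"]],
          n_obs = length(idx),
          n_mothers = length(unique(dd$mother_id[idx])),
          degenerate = FALSE, stringsAsFactors = FALSE
        )
      })
      return(list(row = do.call(rbind, sub_rows), fit = fit))
    }

    L <- as.numeric(names(b) == "exposed")
    ci <- lincom(b, V, L, level)
    mr <- marginal_rates(fit, dd, "exposed")
    row$rate_ratio <- exp(ci[["est"]])
    row$rr_lo <- exp(ci[["lo"]])
    row$rr_hi <- exp(ci[["hi"]])
    row$rate_difference <- mr[["exposed"]] - mr[["unexposed"]]
    row$model_rate_exposed <- mr[["exposed"]]
    row$model_rate_unexposed <- mr[["unexposed"]]
    list(row = row, fit = fit)
  }

  if (by_band && length(bands) > 1L) {
    rows$bands <- fit_one(d, NA_character_, interaction = TRUE)$row
  } else if (by_band && length(bands) == 1L) {
    rows$bands <- fit_one(d, bands, interaction = FALSE)$row
  }
  if (pooled) {
    rows$all <- fit_one(d, "all", interaction = FALSE)$row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL

  if (rd_boot > 0L) {
    bt <- cluster_boot_differences(d, category = category,
                                   value_col = "count", n_boot = rd_boot)
    for (i in seq_len(nrow(out))) {
      bnd <- out$age_band[i]
      sdv <- bt$sd[match(bnd, bt$age_band)]
      if (!is.na(sdv)) {
        out$rd_lo[i] <- out$rd_crude[i] - z * sdv
        out$rd_hi[i] <- out$rd_crude[i] + z * sdv
      }
    }
  }
  out
}

# cluster bootstrap (mothers with replacement) of crude per-band rate or cost
# differences; returns the bootstrap SD per band plus an "all" row.
# Resampling uses multiplicity weights, so a sibship is never split.
cluster_boot_differences <- function(records, category = "any",
                                     value_col = "count", n_boot = 200L) {
  d <- as.data.table(records)
  flag <- paste0("exposed_", category)
  d[, exposed := get(flag)]
  d[, count := as.numeric(get(value_col))]
  mothers <- sort(unique(d$mother_id))
  m <- length(mothers)
  d[, mi := match(mother_id, mothers)]
  bands <- unique(as.character(d$age_band))
  # per-mother sums of numerator and person-years per band x arm cell
  cell <- d[, .(num = sum(count), py = sum(person_years)),
            by = .(mi, age_band = as.character(age_band), exposed)]
  cell_all <- d[, .(num = sum(count), py = sum(person_years)),
                by = .(mi, exposed)][, age_band := "all"]
  cell <- rbind(cell, cell_all)
  cell[, col := paste(age_band, as.integer(exposed), sep = "|")]
  cols <- sort(unique(cell$col))
  Mnum <- matrix(0, nrow = m, ncol = length(cols), dimnames = list(NULL, cols))
  Mpy <- Mnum
  Mnum[cbind(cell$mi, match(cell$col, cols))] <- cell$num
  Mpy[cbind(cell$mi, match(cell$col, cols))] <- cell$py

  diff_from_w <- function(w) {
    num <- drop(w %*% Mnum)
    py <- drop(w %*% Mpy)
    sapply(c(bands, "all"), function(bnd) {
      ce <- paste0(bnd, "|1"); cu <- paste0(bnd, "|0")
      re <- if (ce %in% cols && py[ce] > 0) num[ce] / py[ce] else NA_real_
      ru <- if (cu %in% cols && py[cu] > 0) num[cu] / py[cu] else NA_real_
      re - ru
    })
  }

  boots <- matrix(NA_real_, nrow = n_boot, ncol = length(bands) + 1L)
  for (b in seq_len(n_boot)) {
    w <- tabulate(sample.int(m, m, replace = TRUE), nbins = m)
    boots[b, ] <- diff_from_w(w)
  }
  data.frame(age_band = c(bands, "all"),
             sd = apply(boots, 2L, sd, na.rm = TRUE),
             stringsAsFactors = FALSE)
}
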