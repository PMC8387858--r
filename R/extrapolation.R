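# National excess-cost extrapolation with cluster-bootstrap intervals.
#
# Per band: excess = cost difference (pounds per exposed child per year) x
# exposure prevalence x number of children in the band nationally; the total
# is the sum over the five bands. The interval resamples mothers with
# replacement (children travel with their mother), recomputes the crude band
# cost differences and the national total per resample, and applies the
# normal approximation: point +/- z x SD(bootstrap totals).

#' Synthetic national population table
#'
#' Child population counts per age band (England-scale, synthetic stand-ins
#' for official mid-year estimates) and the exposure prevalence per band.
#'
#' @param prevalence per-band exposure prevalences (recycled scalar allowed).
#' @return data.frame: `age_band`, `n_children`, `mmi_prevalence`.
#' @export
default_population <- function(prevalence = c(0.23, 0.23, 0.22, 0.22, 0.21)) {
  data.frame(
    age_band = age_band_levels(),
    n_children = c(663000L, 2722000L, 3412000L, 2531000L, 2548000L),
    mmi_prevalence = rep_len(prevalence, 5L),
    stringsAsFactors = FALSE
  )
}

validate_population <- function(population) {
  stopifnot(all(c("age_band", "n_children", "mmi_prevalence") %in%
                  names(population)))
  missing_bands <- setdiff(age_band_levels(), population$age_band)
  if (length(missing_bands)) {
    stop("configuration error: population table missing band(s): ",
         paste(missing_bands, collapse = ", "), call. = FALSE)
  }
  if (any(population$mmi_prevalence < 0 | population$mmi_prevalence > 1)) {
    stop("prevalences must lie in [0, 1]", call. = FALSE)
  }
  if (any(population$n_children < 0)) {
    stop("population counts must be non-negative", call. = FALSE)
  }
  invisible(population)
}

#' National annual excess cost (point estimate)
#'
#' @param cost_differences named numeric vector (names = age bands) of cost
#'   differences in pounds per exposed child per year, or a data.frame with
#'   columns `age_band`, `cost_difference`.
#' @param population data.frame with `age_band`, `n_children`,
#'   `mmi_prevalence`; all five bands required.
#' @return list of class `national_estimate`: `per_band` (data.frame with the
#'   band products) and `total` (pounds per year).
#' @export
national_excess <- function(cost_differences, population) {
  validate_population(population)
  if (is.data.frame(cost_differences)) {
    cd <- setNames(cost_differences$cost_difference,
                   cost_differences$age_band)
  } else {
    cd <- cost_differences
  }
  missing_bands <- setdiff(age_band_levels(), names(cd))
  if (length(missing_bands)) {
    stop("configuration error: cost differences missing band(s): ",
         paste(missing_bands, collapse = ", "), call. = FALSE)
  }
  pop <- population[match(age_band_levels(), population$age_band), ]
  per_band <- data.frame(
    age_band = age_band_levels(),
    cost_difference = unname(cd[age_band_levels()]),
    mmi_prevalence = pop$mmi_prevalence,
    n_children = pop$n_children,
    excess = unname(cd[age_band_levels()]) * pop$mmi_prevalence *
      pop$n_children,
    stringsAsFactors = FALSE
  )
  structure(list(per_band = per_band, total = sum(per_band$excess)),
            class = "national_estimate")
}

#' @export
print.national_estimate <- function(x, ...) {
  cat("National annual excess cost\n")
  print(x$per_band, row.names = FALSE)
  cat(sprintf("Total: GBP %s per year\n",
              format(round(x$total), big.mark = ",")))
  if (!is.null(x$ci_low)) {
    cat(sprintf("95%% CI: GBP %s - %s (%d bootstrap resamples)\n",
                format(round(x$ci_low), big.mark = ","),
                format(round(x$ci_high), big.mark = ","), x$n_bootstrap))
  }
  invisible(x)
}

#' Cluster-bootstrap interval for the national excess cost
#'
#' Computes the crude per-band cost-rate differences from per-segment cost
#' records, extrapolates nationally, and attaches a normal-approximation
#' interval from a cluster bootstrap: mothers are resampled with replacement
#' (via multiplicity weights, so a sibship is never split), the band
#' differences and the national total are recomputed per resample, and the
#' interval is point +/- z x SD of the bootstrap totals. Deterministic under a
#' fixed seed.
#'
#' @param cost_records data.frame from [cost_rates()].
#' @param population population table (see [national_excess()]).
#' @param n_boot number of bootstrap resamples (>= 2).
#' @param seed integer seed for the resampling.
#' @param category exposure category name.
#' @param level confidence level.
#' @param ci `"normal"` (default) or `"percentile"`.
#' @return `national_estimate` with `ci_low`, `ci_high`, `n_bootstrap`,
#'   per-band bootstrap SDs (`per_band$boot_sd`) and the vector of bootstrap
#'   totals (`boot_totals`).
#' @export
bootstrap_ci <- function(cost_records, population, n_boot = 1000L, seed = 1L,
                         category = "any", level = 0.95,
                         ci = c("normal", "percentile")) {
  ci <- match.arg(ci)
  if (n_boot < 2L) stop("n_boot must be at least 2", call. = FALSE)
  validate_population(population)
  d <- as.data.table(cost_records)
  flag <- paste0("exposed_", category)
  stopifnot(flag %in% names(d), "cost" %in% names(d))
  d[, exposed := as.integer(get(flag))]
  d[, mother_id := as.character(mother_id)]
  for (arm in 0:1) {
    if (length(unique(d$mother_id[d$exposed == arm])) < 2L) {
      stop("fewer than 2 mother clusters in an exposure arm", call. = FALSE)
    }
  }
  pop <- population[match(age_band_levels(), population$age_band), ]
  scale_vec <- pop$mmi_prevalence * pop$n_children

  mothers <- sort(unique(d$mother_id))
  m <- length(mothers)
  d[, mi := match(mother_id, mothers)]
  cell <- d[, .(num = sum(cost), py = sum(person_years)),
            by = .(mi, age_band = as.character(age_band), exposed)]
  bands <- age_band_levels()
  cell <- cell[age_band %in% bands]
  cell[, col := paste(age_band, exposed, sep = "|")]
  cols <- as.vector(outer(bands, 0:1, paste, sep = "|"))
  Mnum <- matrix(0, nrow = m, ncol = length(cols), dimnames = list(NULL, cols))
  Mpy <- Mnum
  idx <- cbind(cell$mi, match(cell$col, cols))
  Mnum[idx] <- cell$num
  Mpy[idx] <- cell$py

  band_diffs <- function(w) {
    num <- drop(w %*% Mnum)
    py <- drop(w %*% Mpy)
    pe <- py[paste0(bands, "|1")]
    pu <- py[paste0(bands, "|0")]
    re <- ifelse(pe > 0, num[paste0(bands, "|1")] / pe, NA_real_)
    ru <- ifelse(pu > 0, num[paste0(bands, "|0")] / pu, NA_real_)
    unname(re - ru)
  }

  point_diffs <- band_diffs(rep(1, m))
  point_total <- sum(point_diffs * scale_vec)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  boot_totals <- vapply(seq_len(n_boot), function(b) {
    w <- tabulate(sample.int(m, m, replace = TRUE), nbins = m)
    sum(band_diffs(w) * scale_vec)
  }, numeric(1))

  # resamples that empty a band x arm cell are uninformative; they are rare
  # at analysis scale and dropped here
  boot_totals <- boot_totals[!is.na(boot_totals)]
  z <- qnorm(1 - (1 - level) / 2)
  bsd <- sd(boot_totals)
  if (ci == "normal") {
    lo <- point_total - z * bsd
    hi <- point_total + z * bsd
  } else {
    qs <- unname(quantile(boot_totals, c((1 - level) / 2, 1 - (1 - level) / 2)))
    lo <- qs[1]
    hi <- qs[2]
  }

  est <- national_excess(setNames(point_diffs, bands), population)
  est$ci_low <- lo
  est$ci_high <- hi
  est$n_bootstrap <- n_boot
  est$boot_sd <- bsd
  est$boot_totals <- boot_totals
  est
}
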