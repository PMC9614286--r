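#' Wilson score confidence interval for a binomial proportion
#'
#' @param k Number of successes (vectorised).
#' @param n Number of trials.
#' @param conf Confidence level, default 0.95.
#' @return A tibble with columns `low`, `high`, clipped to \[0, 1\].
#' @examples
#' wilson_ci(10, 100)
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  if (any(n == 0)) {
    stop_adt("undefined_prevalence", "Wilson interval undefined for n = 0")
  }
  if (any(k < 0 | k > n)) {
    stop_adt("config", "k must satisfy 0 <= k <= n")
  }
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  tibble::tibble(low = pmax(0, centre - half), high = pmin(1, centre + half))
}

## internal: patients of the episode set, optionally restricted to a region
region_patients <- function(episodes, region = NULL) {
  p <- episodes$patients
  if (!is.null(region)) p <- p[p$region %in% region, , drop = FALSE]
  p
}

year_bounds <- function(year) {
  c(as.Date(sprintf("%d-01-01", year)), as.Date(sprintf("%d-01-01", year + 1)))
}

first_cohort_year <- function(episodes) {
  lubridate::year(min(episodes$patients$first_date))
}

#' Patients with LHRH coverage in a given calendar year
#'
#' A patient is treated in a year iff at least one day of LHRH coverage
#' (dispensation date plus effect of the dose, stockpiling included) falls in
#' that calendar year — a 6-month depot dispensed in December therefore
#' counts the patient as treated in the following year too.
#'
#' @param episodes An `adt_episodes` object.
#' @param year Calendar year.
#' @param region Optional region (or vector of regions) to restrict to.
#' @return Character vector of patient ids (possibly empty; a year wholly
#'   outside the observed coverage raises an `adtgaps_warning_empty_stratum`
#'   warning and returns an empty set).
#' @export
treated_in_year <- function(episodes, year, region = NULL) {
  yb <- year_bounds(year)
  cov <- episodes$coverage
  keep_ids <- region_patients(episodes, region)$patient_id
  cov <- cov[cov$patient_id %in% keep_ids, , drop = FALSE]
  hit <- cov$covered_from < yb[2] & cov$covered_until > yb[1]
  ids <- unique(cov$patient_id[hit])
  if (length(ids) == 0 && nrow(episodes$coverage) > 0) {
    all_cov <- episodes$coverage
    if (yb[2] <= min(all_cov$covered_from) || yb[1] >= max(all_cov$covered_until)) {
      warn_adt("empty_stratum",
               sprintf("year %d lies outside the observed coverage window", year))
    }
  }
  ids
}

## internal: patients with >= 1 off-period day inside the year
intermittent_in_year <- function(episodes, year, region = NULL) {
  yb <- year_bounds(year)
  off <- episodes$off_periods
  keep_ids <- region_patients(episodes, region)$patient_id
  off <- off[off$patient_id %in% keep_ids, , drop = FALSE]
  hit <- off$start_date < yb[2] & off$end_date > yb[1]
  unique(off$patient_id[hit])
}

#' Annual prevalence of intermittent androgen deprivation (P_IAD)
#'
#' Number of patients with at least one off-period day inside the year,
#' divided by the number of patients treated with LHRH analogues in the same
#' year, with a Wilson confidence interval.  The first calendar year of the
#' cohort is refused by default: a patient already in an off period when
#' observation starts cannot be identified as intermittent, so the first
#' year's prevalence is systematically underestimated.
#'
#' @param episodes An `adt_episodes` object (off periods detected).
#' @param year Calendar year (strictly after the cohort's first year unless
#'   `include_first_year = TRUE`).
#' @param region Optional region restriction.
#' @param include_first_year Override the first-year refusal (the estimate is
#'   then flagged `underestimated`).
#' @param conf Confidence level for the Wilson interval.
#' @return One-row tibble: `year`, `region`, `n_treated`, `n_intermittent`,
#'   `p_iad`, `ci_low`, `ci_high`, `underestimated`.
#' @export
annual_p_iad <- function(episodes, year, region = NULL,
                         include_first_year = FALSE, conf = 0.95) {
  fy <- first_cohort_year(episodes)
  if (year <= fy && !include_first_year) {
    stop_adt("first_year",
             sprintf(paste0("year %d is the cohort's first observed year; ",
                            "its prevalence is underestimated (set ",
                            "include_first_year = TRUE to force)"), year),
             year = year)
  }
  denom <- treated_in_year(episodes, year, region)
  if (length(denom) == 0) {
    stop_adt("undefined_prevalence",
             sprintf("no patients treated in year %d%s", year,
                     if (is.null(region)) "" else paste0(" in ", paste(region, collapse = "/"))),
             year = year)
  }
  num <- intersect(intermittent_in_year(episodes, year, region), denom)
  ci <- wilson_ci(length(num), length(denom), conf)
  tibble::tibble(
    year = as.integer(year),
    region = if (is.null(region)) "all" else paste(region, collapse = "+"),
    n_treated = length(denom),
    n_intermittent = length(num),
    p_iad = length(num) / length(denom),
    ci_low = ci$low, ci_high = ci$high,
    underestimated = year <= fy
  )
}

#' Global (ever-intermittent) prevalence over the whole study period
#'
#' Patients with at least one off period anywhere in the window, divided by
#' all included patients.  Note that this overstates the annual prevalence:
#' a patient intermittent in a single year counts here for the whole period,
#' so the global figure exceeds the mean of the annual ones whenever off
#' periods are sparse in time.
#'
#' @inheritParams annual_p_iad
#' @return One-row tibble shaped like [annual_p_iad()] with `year = "all"`.
#' @export
global_p_iad <- function(episodes, region = NULL, conf = 0.95) {
  pats <- region_patients(episodes, region)
  if (nrow(pats) == 0) {
    stop_adt("undefined_prevalence", "empty cohort")
  }
  ever <- intersect(unique(episodes$off_periods$patient_id), pats$patient_id)
  ci <- wilson_ci(length(ever), nrow(pats), conf)
  tibble::tibble(
    year = NA_integer_,
    region = if (is.null(region)) "all" else paste(region, collapse = "+"),
    n_treated = nrow(pats),
    n_intermittent = length(ever),
    p_iad = length(ever) / nrow(pats),
    ci_low = ci$low, ci_high = ci$high,
    underestimated = FALSE
  )
}

#' Mean annual prevalence of intermittency
#'
#' Unweighted arithmetic mean of the annual prevalences.  Either computes
#' the annual values from an `adt_episodes` object, or averages a numeric
#' vector of already-computed annual prevalences.
#'
#' @param x An `adt_episodes` object or a numeric vector of annual
#'   prevalence values.
#' @param ... Passed to methods.
#' @return A single numeric value on the scale of the input (fraction for
#'   episode objects).
#' @export
mean_annual_p_iad <- function(x, ...) UseMethod("mean_annual_p_iad")

#' @rdname mean_annual_p_iad
#' @export
mean_annual_p_iad.numeric <- function(x, ...) {
  if (length(x) == 0) stop_adt("undefined_prevalence", "no annual values supplied")
  mean(x)
}

#' @param years Calendar years to average over (episodes method); defaults to
#'   every observed year after the first.
#' @param region Optional region restriction.
#' @rdname mean_annual_p_iad
#' @export
mean_annual_p_iad.adt_episodes <- function(x, years = NULL, region = NULL, ...) {
  if (is.null(years)) {
    fy <- first_cohort_year(x)
    ly <- lubridate::year(max(x$patients$last_date))
    years <- seq(fy + 1L, ly)
  }
  vals <- purrr::map_dbl(years, function(y) {
    tryCatch(annual_p_iad(x, y, region, include_first_year = TRUE)$p_iad,
             adtgaps_error_undefined_prevalence = function(e) NA_real_)
  })
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) {
    stop_adt("undefined_prevalence", "prevalence undefined in every requested year")
  }
  mean(vals)
}

#' Percentage of time off treatment (%IAD)
#'
#' Total off-period days (over patients with at least one off period)
#' divided by the total days between first and last dispensation.  The
#' denominator defaults to all included patients; restricting it to
#' intermittent patients is available as a sensitivity option.
#'
#' @param episodes An `adt_episodes` object.
#' @param region Optional region restriction (applies to both numerator and
#'   denominator populations).
#' @param scope `"all_patients"` (default) or `"iad_patients_only"` for the
#'   denominator population.
#' @return One-row tibble: `region`, `scope`, `off_days_total`,
#'   `interval_days_total`, `percent_iad` (a fraction).
#' @export
percent_iad <- function(episodes, region = NULL,
                        scope = c("all_patients", "iad_patients_only")) {
  scope <- match.arg(scope)
  pats <- region_patients(episodes, region)
  off <- episodes$off_periods
  off <- off[off$patient_id %in% pats$patient_id, , drop = FALSE]
  denom_pats <- if (scope == "iad_patients_only") {
    pats[pats$patient_id %in% off$patient_id, , drop = FALSE]
  } else {
    pats
  }
  denom <- sum(denom_pats$span_days)
  if (denom == 0) {
    stop_adt("undefined_percent", "zero total interval time in the requested scope")
  }
  tibble::tibble(
    region = if (is.null(region)) "all" else paste(region, collapse = "+"),
    scope = scope,
    off_days_total = sum(off$duration_days),
    interval_days_total = denom,
    percent_iad = sum(off$duration_days) / denom
  )
}

#' Summarise off-period durations
#'
#' Median, interquartile range (type-7 linearly interpolated quantiles),
#' minimum and maximum of off-period durations, converted to months under
#' the episode set's duration policy.
#'
#' @param episodes An `adt_episodes` object.
#' @param region Optional region restriction.
#' @return One-row tibble: `region`, `n_off_periods`, `median_months`,
#'   `iqr_months`, `min_months`, `max_months`; an empty stratum raises an
#'   `adtgaps_warning_empty_stratum` warning and returns zero rows.
#' @export
offperiod_summary <- function(episodes, region = NULL) {
  dpm <- episodes$config$policy$days_per_month
  pats <- region_patients(episodes, region)
  off <- episodes$off_periods
  off <- off[off$patient_id %in% pats$patient_id, , drop = FALSE]
  lab <- if (is.null(region)) "all" else paste(region, collapse = "+")
  if (nrow(off) == 0) {
    warn_adt("empty_stratum", sprintf("no off periods in stratum '%s'", lab))
    return(tibble::tibble(region = character(), n_off_periods = integer(),
                          median_months = double(), iqr_months = double(),
                          min_months = double(), max_months = double()))
  }
  m <- off$duration_days / dpm
  q <- quantile(m, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(
    region = lab,
    n_off_periods = nrow(off),
    median_months = q[2],
    iqr_months = q[3] - q[1],
    min_months = min(m),
    max_months = max(m)
  )
}

#' Year x region prevalence table
#'
#' Computes [annual_p_iad()] for every requested year, for each region and
#' for the pooled cohort, returning one tidy table (the shape behind a
#' per-community prevalence table).  Undefined strata are omitted.
#'
#' @param episodes An `adt_episodes` object.
#' @param years Years to tabulate; default all observed years after the
#'   first (set `include_first_year = TRUE` to prepend the first year,
#'   flagged as underestimated).
#' @param regions Regions to stratify by; default the regions present.
#' @param include_first_year Include the cohort's first year.
#' @param conf Confidence level.
#' @return Tibble with one row per (year, region) stratum plus pooled rows.
#' @export
prevalence_table <- function(episodes, years = NULL, regions = NULL,
                             include_first_year = FALSE, conf = 0.95) {
  fy <- first_cohort_year(episodes)
  ly <- lubridate::year(max(episodes$patients$last_date))
  if (is.null(years)) {
    years <- if (include_first_year) seq(fy, ly) else seq(fy + 1L, ly)
  }
  regions <- regions %||% sort(unique(episodes$patients$region))
  strata <- tidyr::expand_grid(year = years, region = c(list(NULL), as.list(regions)))
  purrr::pmap(strata, function(year, region) {
    tryCatch(
      annual_p_iad(episodes, year, region,
                   include_first_year = include_first_year, conf = conf),
      adtgaps_error_undefined_prevalence = function(e) NULL,
      adtgaps_error_first_year = function(e) NULL
    )
  }) %>%
    purrr::compact() %>%
    purrr::list_rbind()
}

#' Pearson chi-square test of independence on a contingency table
#'
#' Without continuity correction, as appropriate for large registry samples;
#' degrees of freedom `(r - 1)(c - 1)`.  Used to compare presence/absence of
#' intermittency across regions or years.
#'
#' @param table Matrix of counts, at least 2 x 2.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
chi_square_independence <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) {
    stop_adt("degenerate_table", "contingency table must be at least 2 x 2")
  }
  if (any(table < 0) || any(!is.finite(table))) {
    stop_adt("degenerate_table", "counts must be finite and non-negative")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop_adt("degenerate_table", "zero marginal in contingency table")
  }
  res <- suppressWarnings(chisq.test(table, correct = correct))
  tibble::tibble(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = unname(res$p.value))
}
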