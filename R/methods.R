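#' @export
print.adt_episodes <- function(x, ...) {
  cat("ADT treatment episodes\n")
  cat(sprintf("  patients: %d, intervals: %d, off periods: %d\n",
              nrow(x$patients), nrow(x$intervals), nrow(x$off_periods)))
  cat(sprintf("  min gap: %d days, carry-forward: %s\n",
              x$config$min_gap_days, x$config$carry_forward))
  invisible(x)
}

#' Tidy an episode set into one row per off period
#'
#' @param x An `adt_episodes` object.
#' @param ... Unused.
#' @return Tibble of off periods joined with patient region and span.
#' @export
tidy.adt_episodes <- function(x, ...) {
  x$off_periods %>%
    dplyr::left_join(
      dplyr::select(x$patients, "patient_id", "region", "span_days"),
      by = "patient_id"
    )
}

#' One-row summary of an episode set
#'
#' @param x An `adt_episodes` object.
#' @param ... Unused.
#' @return Tibble with patient, interval and off-period counts, the
#'   ever-intermittent fraction and the overall fraction of span days spent
#'   off treatment.
#' @export
glance.adt_episodes <- function(x, ...) {
  tibble::tibble(
    n_patients = nrow(x$patients),
    n_intervals = nrow(x$intervals),
    n_off_periods = nrow(x$off_periods),
    ever_intermittent = dplyr::n_distinct(x$off_periods$patient_id) /
      nrow(x$patients),
    fraction_days_off = sum(x$off_periods$duration_days) /
      sum(x$patients$span_days)
  )
}

#' Tidy a pipeline run into its prevalence table
#'
#' @param x An `adt_results` object.
#' @param ... Unused.
#' @return The year x region prevalence tibble.
#' @export
tidy.adt_results <- function(x, ...) {
  x$prevalence
}

#' One-row summary of a pipeline run
#'
#' @param x An `adt_results` object.
#' @param ... Unused.
#' @return Tibble with the headline estimates of the run.
#' @export
glance.adt_results <- function(x, ...) {
  overall <- x$percent_iad[x$percent_iad$region == "all", ]
  tibble::tibble(
    n_patients = x$global_prevalence$n_treated,
    global_p_iad = x$global_prevalence$p_iad,
    mean_annual_p_iad = x$mean_annual_p_iad,
    percent_iad = overall$percent_iad,
    n_off_periods = nrow(x$episodes$off_periods)
  )
}
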