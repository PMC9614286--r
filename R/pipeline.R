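#' Simulate a cohort and write it to disk
#'
#' Writes `records.csv`, `truth_patients.csv`, `truth_off_periods.csv` and a
#' machine-readable echo of the resolved configuration (`config.json`) to
#' `out_dir`.  Rerunning with the same configuration reproduces the files
#' byte for byte.
#'
#' @param config An [simulate_config()].
#' @param out_dir Output directory (created if absent).
#' @return The `adt_cohort` object, invisibly.
#' @export
adt_simulate <- function(config = simulate_config(), out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_adt("io", sprintf("cannot create output directory: %s", out_dir))
  }
  cohort <- simulate_cohort(config)
  write_records(cohort$records, file.path(out_dir, "records.csv"))
  readr::write_csv(cohort$truth$patients,
                   file.path(out_dir, "truth_patients.csv"), progress = FALSE)
  readr::write_csv(cohort$truth$off_periods,
                   file.path(out_dir, "truth_off_periods.csv"), progress = FALSE)
  echo <- config
  echo$window_start <- as.character(echo$window_start)
  echo$window_end <- as.character(echo$window_end)
  jsonlite::write_json(unclass(echo), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cohort)
}

#' Run the full episode-and-prevalence pipeline
#'
#' Executes the stages in order — exclusion filters, episode construction,
#' off-period detection, prevalence and off-period metrics, cost accounting
#' — and returns every result table in one object.  All tunable analysis
#' decisions (minimum gap, days per month, carry-forward, denominator
#' scope, confidence level) are taken from the arguments and echoed in the
#' result, so a run documents itself.
#'
#' @param records A dispensation tibble or a path to a records CSV.
#' @param formulary An [adt_formulary()].
#' @param engine An [engine_config()].
#' @param excluded_region_years Optional tibble (`region`, `year`) of strata
#'   excluded from the analysis, and from cost totals.
#' @param denominator_scope Denominator population for the percentage of
#'   time off treatment; see [percent_iad()].
#' @param include_first_year Include the cohort's first calendar year in the
#'   annual prevalence table (flagged as underestimated).
#' @param conf Confidence level for Wilson intervals.
#' @param out_dir Optional directory; when given, every table is written as
#'   CSV together with the exclusion log (JSON and text) and a config echo.
#' @return A list of class `adt_results`: `exclusion_log`, `episodes`,
#'   `patients` (with ever-IAD regimen and age), `prevalence` (year x region
#'   table), `global_prevalence`, `mean_annual_p_iad`, `percent_iad` (overall
#'   and per region), `offperiod_summary`, `costs_by_year_class`,
#'   `costs_by_year_drug`, `cost_per_dispensation`, `qc_flags`, `settings`.
#' @export
adt_run <- function(records, formulary = adt_formulary(),
                    engine = engine_config(),
                    excluded_region_years = NULL,
                    denominator_scope = c("all_patients", "iad_patients_only"),
                    include_first_year = FALSE, conf = 0.95,
                    out_dir = NULL) {
  denominator_scope <- match.arg(denominator_scope)
  if (is.character(records)) records <- read_records(records)

  filt <- apply_exclusions(records, formulary, excluded_region_years)
  episodes <- build_episodes(filt$records, formulary, engine)
  regions <- sort(unique(episodes$patients$region))

  prevalence <- prevalence_table(episodes, include_first_year = include_first_year,
                                 conf = conf)
  global_prev <- global_p_iad(episodes, conf = conf)
  mean_annual <- mean_annual_p_iad(episodes)

  piad <- dplyr::bind_rows(
    percent_iad(episodes, scope = denominator_scope),
    purrr::map(regions, function(r) {
      tryCatch(percent_iad(episodes, region = r, scope = denominator_scope),
               adtgaps_error_undefined_percent = function(e) NULL)
    }) %>% purrr::compact() %>% purrr::list_rbind()
  )

  offsum <- suppressWarnings(dplyr::bind_rows(
    offperiod_summary(episodes),
    purrr::map(regions, ~ offperiod_summary(episodes, .x)) %>% purrr::list_rbind()
  ))

  costs_class <- annual_costs(filt$records, c("year", "drug_class"),
                              excluded_region_years, formulary)
  costs_drug <- annual_costs(filt$records, c("year", "region", "drug"),
                             excluded_region_years, formulary)
  years <- sort(unique(lubridate::year(filt$records$dispense_date)))
  cpd <- purrr::map(years, ~ mean_cost_per_dispensation(filt$records, .x)) %>%
    purrr::list_rbind()

  ever_iad <- unique(episodes$off_periods$patient_id)
  patients <- episodes$patients %>%
    dplyr::mutate(
      regimen = ifelse(.data$patient_id %in% ever_iad, "IAD", "CAD"),
      age = floor(lubridate::time_length(
        lubridate::interval(.data$birth_date, .data$first_date), "years"))
    )

  settings <- list(
    min_gap_days = engine$min_gap_days,
    carry_forward = engine$carry_forward,
    days_per_month = engine$policy$days_per_month,
    denominator_scope = denominator_scope,
    ci_method = "wilson",
    conf = conf,
    include_first_year = include_first_year,
    excluded_region_years = excluded_region_years
  )
  settings$run_id <- rlang::hash(settings)

  res <- structure(list(
    exclusion_log = filt$log,
    episodes = episodes,
    patients = patients,
    prevalence = prevalence,
    global_prevalence = global_prev,
    mean_annual_p_iad = mean_annual,
    percent_iad = piad,
    offperiod_summary = offsum,
    costs_by_year_class = costs_class,
    costs_by_year_drug = costs_drug,
    cost_per_dispensation = cpd,
    qc_flags = qc_region_years(filt$records),
    settings = settings
  ), class = "adt_results")

  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

write_results <- function(res, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_adt("io", sprintf("cannot create output directory: %s", out_dir))
  }
  w <- function(x, name) readr::write_csv(x, file.path(out_dir, name),
                                          progress = FALSE)
  w(res$patients, "patients.csv")
  w(res$episodes$off_periods, "off_periods.csv")
  w(res$prevalence, "prevalence.csv")
  w(res$global_prevalence, "global_prevalence.csv")
  w(res$percent_iad, "percent_iad.csv")
  w(res$offperiod_summary, "offperiod_summary.csv")
  w(res$costs_by_year_class, "costs_by_year_class.csv")
  w(res$costs_by_year_drug, "costs_by_year_drug.csv")
  w(res$cost_per_dispensation, "cost_per_dispensation.csv")
  w(res$qc_flags, "qc_region_years.csv")
  log <- res$exclusion_log
  jsonlite::write_json(
    list(n_input_records = log$n_input_records,
         n_input_patients = log$n_input_patients,
         excluded_under18 = log$excluded_under18,
         excluded_antiandrogen_only = log$excluded_antiandrogen_only,
         excluded_region_years = log$excluded_region_years,
         excluded_region_year_patients = log$excluded_region_year_patients,
         n_final_patients = log$n_final_patients,
         n_final_records = log$n_final_records),
    file.path(out_dir, "exclusion_log.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  writeLines(utils::capture.output(print(log)),
             file.path(out_dir, "exclusion_log.txt"))
  jsonlite::write_json(res$settings, file.path(out_dir, "settings.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Render the summary charts for a pipeline run
#'
#' Builds the three standard figures — annual prevalence trend, cost by year
#' and drug, and the age distribution by regimen in decade bins (reporting
#' the shares of patients over 70 and over 80) — from an `adt_results`
#' object or a directory written by [adt_run()].  Charts with no underlying
#' data are skipped with a warning.
#'
#' @param results An `adt_results` object or a directory path.
#' @param out_dir Optional directory to save the charts as PNG.
#' @return A list with ggplot objects `prevalence_trend`, `cost_trend`,
#'   `age_distribution` (possibly `NULL`) and a tibble `age_shares`.
#' @export
adt_report <- function(results, out_dir = NULL) {
  if (is.character(results)) {
    need <- c("prevalence.csv", "costs_by_year_drug.csv", "patients.csv")
    absent <- need[!file.exists(file.path(results, need))]
    if (length(absent)) {
      stop_adt("io", sprintf("missing result tables: %s",
                             paste(absent, collapse = ", ")))
    }
    results <- list(
      prevalence = readr::read_csv(file.path(results, "prevalence.csv"),
                                   show_col_types = FALSE, progress = FALSE),
      costs_by_year_drug = readr::read_csv(
        file.path(results, "costs_by_year_drug.csv"),
        show_col_types = FALSE, progress = FALSE),
      patients = readr::read_csv(file.path(results, "patients.csv"),
                                 show_col_types = FALSE, progress = FALSE)
    )
  }
  p_trend <- if (nrow(results$prevalence) == 0) {
    warn("prevalence table is empty; trend chart skipped")
    NULL
  } else {
    plot_prevalence_trend(results$prevalence)
  }
  p_cost <- if (nrow(results$costs_by_year_drug) == 0) {
    warn("cost table is empty; cost chart skipped")
    NULL
  } else {
    plot_cost_trend(results$costs_by_year_drug)
  }
  p_age <- plot_age_distribution(results$patients)
  shares <- results$patients %>%
    dplyr::group_by(.data$regimen) %>%
    dplyr::summarise(n = dplyr::n(),
                     share_over_70 = mean(.data$age > 70),
                     share_over_80 = mean(.data$age > 80), .groups = "drop")
  out <- list(prevalence_trend = p_trend, cost_trend = p_cost,
              age_distribution = p_age, age_shares = shares)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (nm in c("prevalence_trend", "cost_trend", "age_distribution")) {
      if (!is.null(out[[nm]])) {
        ggplot2::ggsave(file.path(out_dir, paste0(nm, ".png")), out[[nm]],
                        width = 7, height = 4.5, dpi = 150)
      }
    }
  }
  out
}

#' @export
print.adt_results <- function(x, ...) {
  cat("ADT intermittency analysis\n")
  cat(sprintf("  patients: %d (%d ever intermittent, %.1f%%)\n",
              x$global_prevalence$n_treated, x$global_prevalence$n_intermittent,
              100 * x$global_prevalence$p_iad))
  cat(sprintf("  mean annual P_IAD: %.1f%%\n", 100 * x$mean_annual_p_iad))
  overall <- x$percent_iad[x$percent_iad$region == "all", ]
  cat(sprintf("  %%IAD (time off treatment): %.1f%%\n",
              100 * overall$percent_iad))
  invisible(x)
}
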