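#' Apply the study inclusion/exclusion rules
#'
#' Removes, in order: (a) all records of patients younger than `age_cutoff`
#' years at their first dispensation; (b) all records of patients with no
#' LHRH analogue dispensation at all (antiandrogen-only subjects, for whom
#' chemical castration is not guaranteed); (c) all records falling in
#' explicitly excluded (region, year) strata — e.g. a region-year with a
#' known-incomplete electronic record system — dropping and counting any
#' patient left with zero records.  Antiandrogen rows of retained patients
#' are kept: they contribute to combination counts and costs but never to
#' coverage.
#'
#' @param records Dispensation tibble (canonical schema, see [read_records()]).
#' @param formulary An [adt_formulary()] used to classify rows by ATC code.
#' @param excluded_region_years Optional tibble or data frame with columns
#'   `region` and `year` listing strata to drop; exclusion is always
#'   explicit, never automatic (see [qc_region_years()] for the advisory
#'   report).
#' @param age_cutoff Minimum age in years at first dispensation (default 18).
#' @return A list with `records` (the filtered tibble) and `log`, an
#'   `adt_exclusion_log` accounting for every input patient exactly once.
#' @export
apply_exclusions <- function(records, formulary = adt_formulary(),
                             excluded_region_years = NULL, age_cutoff = 18) {
  records <- dplyr::as_tibble(records)
  n_input_records <- nrow(records)
  n_input_patients <- dplyr::n_distinct(records$patient_id)

  if (n_input_records == 0) {
    log <- new_exclusion_log(0L, 0L, 0L, 0L,
                             empty_region_year_tbl(), 0L, 0L, 0L)
    return(list(records = records, log = log))
  }

  cls <- classify_drug(records$atc_code)
  records$.drug_class <- cls

  # (a) age at first dispensation
  first_disp <- records %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::summarise(birth_date = dplyr::first(.data$birth_date),
                     first_date = min(.data$dispense_date), .groups = "drop") %>%
    dplyr::mutate(age_first = floor(lubridate::time_length(
      lubridate::interval(.data$birth_date, .data$first_date), "years")))
  under <- first_disp$patient_id[first_disp$age_first < age_cutoff]
  records <- records[!records$patient_id %in% under, , drop = FALSE]

  # (b) antiandrogen-only patients
  has_lhrh <- records %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::summarise(any_lhrh = any(.data$.drug_class == "lhrh_analogue"),
                     .groups = "drop")
  aa_only <- has_lhrh$patient_id[!has_lhrh$any_lhrh]
  records <- records[!records$patient_id %in% aa_only, , drop = FALSE]

  # (c) configured region-year exclusions
  dropped_strata <- empty_region_year_tbl()
  n_ry_patients <- 0L
  if (!is.null(excluded_region_years) && nrow(excluded_region_years) > 0) {
    ex <- dplyr::as_tibble(excluded_region_years)
    stopifnot(all(c("region", "year") %in% names(ex)))
    before <- unique(records$patient_id)
    records$.year <- lubridate::year(records$dispense_date)
    hit <- paste(records$region, records$.year) %in% paste(ex$region, ex$year)
    dropped_strata <- records[hit, , drop = FALSE] %>%
      dplyr::count(region = .data$region, year = .data$.year, name = "n_records")
    records <- records[!hit, , drop = FALSE]
    records$.year <- NULL
    gone <- setdiff(before, unique(records$patient_id))
    n_ry_patients <- length(gone)
  }

  records$.drug_class <- NULL
  log <- new_exclusion_log(
    n_input_records, n_input_patients,
    excluded_under18 = length(under),
    excluded_antiandrogen_only = length(aa_only),
    excluded_region_years = dropped_strata,
    excluded_region_year_patients = n_ry_patients,
    n_final_patients = dplyr::n_distinct(records$patient_id),
    n_final_records = nrow(records)
  )
  list(records = records, log = log)
}

empty_region_year_tbl <- function() {
  tibble::tibble(region = character(), year = integer(), n_records = integer())
}

new_exclusion_log <- function(n_input_records, n_input_patients,
                              excluded_under18, excluded_antiandrogen_only,
                              excluded_region_years,
                              excluded_region_year_patients,
                              n_final_patients, n_final_records) {
  structure(list(
    n_input_records = as.integer(n_input_records),
    n_input_patients = as.integer(n_input_patients),
    excluded_under18 = as.integer(excluded_under18),
    excluded_antiandrogen_only = as.integer(excluded_antiandrogen_only),
    excluded_region_years = excluded_region_years,
    excluded_region_year_patients = as.integer(excluded_region_year_patients),
    n_final_patients = as.integer(n_final_patients),
    n_final_records = as.integer(n_final_records)
  ), class = "adt_exclusion_log")
}

#' @export
print.adt_exclusion_log <- function(x, ...) {
  cat("Cohort exclusion log\n")
  cat(sprintf("  input:  %d records, %d patients\n",
              x$n_input_records, x$n_input_patients))
  cat(sprintf("  - under-age at first dispensation: %d patients\n",
              x$excluded_under18))
  cat(sprintf("  - antiandrogen-only:               %d patients\n",
              x$excluded_antiandrogen_only))
  if (nrow(x$excluded_region_years)) {
    for (i in seq_len(nrow(x$excluded_region_years))) {
      cat(sprintf("  - dropped stratum %s/%d: %d records\n",
                  x$excluded_region_years$region[i],
                  x$excluded_region_years$year[i],
                  x$excluded_region_years$n_records[i]))
    }
    cat(sprintf("  - patients emptied by stratum drops: %d\n",
                x$excluded_region_year_patients))
  }
  cat(sprintf("  final:  %d records, %d patients\n",
              x$n_final_records, x$n_final_patients))
  invisible(x)
}

#' Flag region-years with suspiciously low record counts
#'
#' Advisory quality-control report: within each region observed for at least
#' three calendar years, flags any year whose record count falls below half
#' of that region's median annual count (the signature of an incomplete
#' electronic dispensation system).  Exclusion itself is always explicit via
#' the `excluded_region_years` argument of [apply_exclusions()].
#'
#' @param records Dispensation tibble.
#' @return Tibble with columns `region`, `year`, `n_records`,
#'   `region_median` (possibly zero rows).
#' @export
qc_region_years <- function(records) {
  if (nrow(records) == 0) {
    stop_adt("config", "qc_region_years needs at least one record")
  }
  records %>%
    dplyr::count(region = .data$region,
                 year = lubridate::year(.data$dispense_date),
                 name = "n_records") %>%
    dplyr::group_by(.data$region) %>%
    dplyr::mutate(n_years = dplyr::n(),
                  region_median = median(.data$n_records)) %>%
    dplyr::ungroup() %>%
    dplyr::filter(.data$n_years >= 3,
                  .data$n_records < 0.5 * .data$region_median) %>%
    dplyr::select("region", "year", "n_records", "region_median")
}
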