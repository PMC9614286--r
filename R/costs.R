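#' Aggregate hormonal-treatment expenditure
#'
#' Sums dispensation costs per stratum and normalises as euros per
#' dispensation.  Costs are attributed to the calendar year of the dispense
#' date.  Strata listed in `excluded_region_years` (e.g. a region with a
#' known-incomplete first year) are dropped from all totals and reported in
#' the `excluded_strata` attribute.
#'
#' @param records Dispensation tibble (LHRH and antiandrogen rows).
#' @param group_by Character subset of `c("year", "region", "drug",
#'   "drug_class")` defining the strata; default year by drug class.
#' @param excluded_region_years Optional tibble with columns `region`, `year`.
#' @param formulary An [adt_formulary()] for drug-name canonicalisation and
#'   ATC classification.
#' @return A tibble of class `adt_costs`, one row per stratum, with
#'   `n_dispensations`, `total_eur`, `eur_per_dispensation`, sorted by the
#'   grouping columns; the dropped strata (with record counts) are attached
#'   as attribute `excluded_strata`.
#' @export
annual_costs <- function(records, group_by = c("year", "drug_class"),
                         excluded_region_years = NULL,
                         formulary = adt_formulary()) {
  allowed <- c("year", "region", "drug", "drug_class")
  if (!all(group_by %in% allowed)) {
    stop_adt("config", paste("group_by must be a subset of:",
                             paste(allowed, collapse = ", ")))
  }
  records <- dplyr::as_tibble(records)
  if (nrow(records) == 0) {
    out <- tibble::tibble(n_dispensations = integer(0),
                          total_eur = double(0),
                          eur_per_dispensation = double(0))
    attr(out, "excluded_strata") <- empty_region_year_tbl()
    class(out) <- c("adt_costs", class(out))
    return(out)
  }
  if (any(records$cost_eur < 0, na.rm = TRUE) || anyNA(records$cost_eur)) {
    bad <- which(is.na(records$cost_eur) | records$cost_eur < 0)
    stop_adt("invalid_cost",
             sprintf("negative or missing cost in rows: %s",
                     paste(head(bad, 5), collapse = ", ")),
             rows = bad)
  }
  records <- records %>%
    dplyr::mutate(year = lubridate::year(.data$dispense_date),
                  drug = canonical_drug_name(.data$drug_name, formulary),
                  drug_class = classify_drug(.data$atc_code))

  excluded <- empty_region_year_tbl()
  if (!is.null(excluded_region_years) && nrow(excluded_region_years) > 0) {
    ex <- dplyr::as_tibble(excluded_region_years)
    hit <- paste(records$region, records$year) %in% paste(ex$region, ex$year)
    excluded <- records[hit, , drop = FALSE] %>%
      dplyr::count(region = .data$region, year = .data$year, name = "n_records")
    records <- records[!hit, , drop = FALSE]
  }

  out <- records %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) %>%
    dplyr::summarise(n_dispensations = dplyr::n(),
                     total_eur = sum(.data$cost_eur), .groups = "drop") %>%
    dplyr::mutate(eur_per_dispensation = .data$total_eur / .data$n_dispensations) %>%
    dplyr::arrange(dplyr::across(dplyr::all_of(group_by)))
  attr(out, "excluded_strata") <- excluded
  class(out) <- c("adt_costs", class(out))
  out
}

#' Mean and SD of the per-dispensation cost in a year
#'
#' Pools LHRH analogue and antiandrogen dispensations by default; pass
#' `drug_class` to restrict.  The SD is the sample standard deviation.
#'
#' @param records Dispensation tibble.
#' @param year Calendar year.
#' @param drug_class Optional `"lhrh_analogue"` or `"antiandrogen"` filter.
#' @return One-row tibble: `year`, `n_dispensations`, `mean_eur`, `sd_eur`;
#'   an empty year raises `adtgaps_warning_empty_stratum` and returns a row
#'   of `NA`s with `n_dispensations = 0`.
#' @export
mean_cost_per_dispensation <- function(records, year, drug_class = NULL) {
  rows <- records[lubridate::year(records$dispense_date) == year, , drop = FALSE]
  if (!is.null(drug_class)) {
    rows <- rows[classify_drug(rows$atc_code) == drug_class, , drop = FALSE]
  }
  if (nrow(rows) == 0) {
    warn_adt("empty_stratum", sprintf("no dispensations in year %d", year))
    return(tibble::tibble(year = as.integer(year), n_dispensations = 0L,
                          mean_eur = NA_real_, sd_eur = NA_real_))
  }
  tibble::tibble(
    year = as.integer(year),
    n_dispensations = nrow(rows),
    mean_eur = mean(rows$cost_eur),
    sd_eur = if (nrow(rows) > 1) sd(rows$cost_eur) else 0
  )
}
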