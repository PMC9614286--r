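#' Episode-engine configuration
#'
#' @param min_gap_days Minimum uncovered run, in days, for a gap to count as
#'   a potentially intermittent interval time (PIIT).  Default 91 days,
#'   i.e. three nominal months under the default day policy — a deliberately
#'   conservative threshold for calling a gap intermittency.
#' @param carry_forward If `TRUE` (default), unexpired coverage from an early
#'   refill is not forfeited: the coverage end after dose *i* is the maximum
#'   of the previous coverage end and `date_i + eld_i` (stockpiling).
#' @param policy A [duration_policy()] used to convert formulary months to days.
#' @return A list of class `adt_engine_config`.
#' @export
engine_config <- function(min_gap_days = 91L, carry_forward = TRUE,
                          policy = duration_policy()) {
  min_gap_days <- as.integer(min_gap_days)
  if (is.na(min_gap_days) || min_gap_days < 1L) {
    stop_adt("config", "min_gap_days must be a positive integer")
  }
  structure(list(min_gap_days = min_gap_days,
                 carry_forward = isTRUE(carry_forward),
                 policy = policy),
            class = "adt_engine_config")
}

## internal: keep LHRH rows, attach per-row coverage days, merge same-day rows
prepare_lhrh <- function(records, formulary, config) {
  records <- dplyr::as_tibble(records)
  cls <- classify_drug(records$atc_code)
  lhrh <- records[cls == "lhrh_analogue", , drop = FALSE]
  if (nrow(lhrh) == 0) {
    stop_adt("config", "no LHRH analogue dispensations in input")
  }
  m <- match_formulary(formulary, lhrh$drug_name, lhrh$dose_mg)
  if (any(!m$known)) {
    i <- which(!m$known)[1]
    stop_adt("unknown_drug",
             sprintf("patient %s: drug not in formulary: '%s'",
                     lhrh$patient_id[i], lhrh$drug_name[i]),
             patient_id = lhrh$patient_id[i], drug_name = lhrh$drug_name[i],
             dose_mg = lhrh$dose_mg[i])
  }
  if (any(m$idx < 0)) {
    i <- which(m$idx < 0)[1]
    stop_adt("unknown_dose",
             sprintf("patient %s: dose not listed for '%s': %g mg",
                     lhrh$patient_id[i], m$drug[i], lhrh$dose_mg[i]),
             patient_id = lhrh$patient_id[i], drug_name = m$drug[i],
             dose_mg = lhrh$dose_mg[i])
  }
  dur_days <- months_to_days(formulary$duration_months[m$idx], config$policy)
  n_units <- if ("n_units" %in% names(lhrh)) lhrh$n_units else 1L
  lhrh %>%
    dplyr::mutate(eld_days = dur_days * as.integer(n_units)) %>%
    dplyr::group_by(.data$patient_id, .data$dispense_date) %>%
    dplyr::summarise(
      birth_date = dplyr::first(.data$birth_date),
      region = dplyr::first(.data$region),
      eld_days = sum(.data$eld_days),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$patient_id, .data$dispense_date)
}

#' Build per-patient interval times from LHRH dispensations
#'
#' An interval time (IntT) is the period between two consecutive LHRH
#' dispensations of one patient.  Each dispensation confers coverage for the
#' effect of the last dose (ELD): the formulary duration times the number of
#' dispensed units.  With carry-forward, the coverage end after a dose is the
#' running maximum of `dispense_date + eld_days`, so early refills stockpile.
#' The uncovered days of an interval are the days between its coverage end
#' and the next dispensation (never negative).  Same-day dispensations are
#' merged with their coverage summed.  Antiandrogen rows never contribute
#' coverage and are ignored here.
#'
#' @param records A dispensation tibble (multiple patients allowed) with
#'   columns `patient_id`, `birth_date`, `region`, `dispense_date`,
#'   `drug_name`, `atc_code`, `dose_mg`, `n_units`.
#' @param formulary An [adt_formulary()].
#' @param config An [engine_config()].
#' @return An object of class `adt_episodes`: a list with tibbles
#'   `patients` (one row per patient with `first_date`, `last_date`,
#'   `span_days`, `n_dispensations`), `intervals` (one row per consecutive
#'   dispensation pair with `length_days`, `eld_days`, `uncovered_days`,
#'   `coverage_end`), `coverage` (the union of covered day ranges, half-open
#'   end), `off_periods` (empty until [detect_piit()]), and the `config`.
#' @examples
#' fmt <- adt_formulary()
#' rec <- tibble::tibble(
#'   patient_id = "P1", birth_date = as.Date("1940-01-01"), region = "Madrid",
#'   dispense_date = as.Date("2012-01-01") + c(0, 200),
#'   drug_name = "leuprorelin", atc_code = "L02AE02", dose_mg = 11.25,
#'   n_units = 1L, cost_eur = 200
#' )
#' build_intervals(rec, fmt)$intervals
#' @export
build_intervals <- function(records, formulary = adt_formulary(),
                            config = engine_config()) {
  doses <- prepare_lhrh(records, formulary, config)

  doses <- doses %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::mutate(
      cov_end = if (config$carry_forward) {
        cummax(as.integer(.data$dispense_date) + .data$eld_days)
      } else {
        as.integer(.data$dispense_date) + .data$eld_days
      },
      next_date = dplyr::lead(.data$dispense_date)
    ) %>%
    dplyr::ungroup()

  patients <- doses %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::summarise(
      birth_date = dplyr::first(.data$birth_date),
      region = dplyr::first(.data$region),
      first_date = min(.data$dispense_date),
      last_date = max(.data$dispense_date),
      n_dispensations = dplyr::n(),
      span_days = as.integer(max(.data$dispense_date) - min(.data$dispense_date)),
      .groups = "drop"
    )

  intervals <- doses %>%
    dplyr::filter(!is.na(.data$next_date)) %>%
    dplyr::mutate(
      start_date = .data$dispense_date,
      end_date = .data$next_date,
      length_days = as.integer(.data$next_date - .data$dispense_date),
      uncovered_days = pmax(0L, as.integer(.data$next_date) - .data$cov_end),
      coverage_end = as.Date(pmin(as.integer(.data$next_date), .data$cov_end),
                             origin = "1970-01-01")
    ) %>%
    dplyr::select("patient_id", "start_date", "end_date", "length_days",
                  "eld_days", "uncovered_days", "coverage_end")

  # union of covered day ranges [dispense_date, dispense_date + eld), merged
  coverage <- doses %>%
    dplyr::mutate(seg_start = as.integer(.data$dispense_date),
                  seg_end = as.integer(.data$dispense_date) + .data$eld_days) %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::arrange(.data$seg_start, .by_group = TRUE) %>%
    dplyr::mutate(block = cumsum(.data$seg_start >
                                   dplyr::lag(cummax(.data$seg_end),
                                              default = .data$seg_start[1] - 1L))) %>%
    dplyr::group_by(.data$patient_id, .data$block) %>%
    dplyr::summarise(seg_start = min(.data$seg_start),
                     seg_end = max(.data$seg_end), .groups = "drop") %>%
    dplyr::transmute(
      patient_id = .data$patient_id,
      covered_from = as.Date(.data$seg_start, origin = "1970-01-01"),
      covered_until = as.Date(.data$seg_end, origin = "1970-01-01")
    )

  structure(
    list(patients = patients, intervals = intervals, coverage = coverage,
         off_periods = tibble::tibble(
           patient_id = character(), start_date = as.Date(character()),
           end_date = as.Date(character()), duration_days = integer()
         ),
         config = config),
    class = "adt_episodes"
  )
}

#' Detect potentially intermittent interval times (off periods)
#'
#' Every interval whose uncovered run is at least `min_gap_days` long yields
#' one off period, anchored at the day coverage ends and terminating at the
#' next dispensation (a confirmed re-initiation).  The open-ended period
#' after a patient's final dispensation is never an off period: a stop
#' without restart (death, progression, true discontinuation) is not
#' intermittency.
#'
#' @param episodes An `adt_episodes` object from [build_intervals()].
#' @param config Optional [engine_config()] overriding the one stored in
#'   `episodes` (useful for sensitivity analysis on the minimum gap).
#' @return `episodes` with `off_periods` populated (one row per off period,
#'   ordered by patient and start date).
#' @export
detect_piit <- function(episodes, config = NULL) {
  stopifnot(inherits(episodes, "adt_episodes"))
  config <- config %||% episodes$config
  off <- episodes$intervals %>%
    dplyr::filter(.data$uncovered_days >= config$min_gap_days) %>%
    dplyr::transmute(
      patient_id = .data$patient_id,
      start_date = .data$end_date - .data$uncovered_days,
      end_date = .data$end_date,
      duration_days = as.integer(.data$uncovered_days)
    ) %>%
    dplyr::arrange(.data$patient_id, .data$start_date)
  episodes$off_periods <- off
  episodes$config <- config
  episodes
}

#' Build intervals and detect off periods in one call
#'
#' Convenience wrapper: [build_intervals()] followed by [detect_piit()].
#'
#' @inheritParams build_intervals
#' @return An `adt_episodes` object with off periods populated.
#' @export
build_episodes <- function(records, formulary = adt_formulary(),
                           config = engine_config()) {
  detect_piit(build_intervals(records, formulary, config))
}

#' Brute-force per-day coverage oracle
#'
#' Marks every calendar day of a window as covered or not, by direct union
#' of the `[dispense_date, dispense_date + eld_days)` coverage windows of one
#' patient's LHRH dispensations.  Intended as an independent cross-check of
#' the interval arithmetic in [build_intervals()]; quadratic in window
#' length, so use on small inputs.
#'
#' @param records Dispensation records for a single patient.
#' @param formulary An [adt_formulary()].
#' @param window Date vector of length 2 covering all records.
#' @param config An [engine_config()] (only the duration policy is used).
#' @return A tibble with one row per calendar day: `day`, `covered`.
#' @export
day_grid_oracle <- function(records, formulary = adt_formulary(),
                            window, config = engine_config()) {
  stopifnot(length(unique(records$patient_id)) == 1)
  doses <- prepare_lhrh(records, formulary, config)
  days <- seq(as.Date(window[1]), as.Date(window[2]), by = "day")
  covered <- rep(FALSE, length(days))
  for (i in seq_len(nrow(doses))) {
    hit <- days >= doses$dispense_date[i] &
      days < doses$dispense_date[i] + doses$eld_days[i]
    covered <- covered | hit
  }
  tibble::tibble(day = days, covered = covered)
}

#' Maximal uncovered runs from a day grid
#'
#' Extracts the maximal runs of uncovered days that lie strictly between a
#' patient's first and last dispensation dates and are at least
#' `min_gap_days` long — the oracle's version of [detect_piit()].
#'
#' @param grid Output of [day_grid_oracle()].
#' @param first_date,last_date The patient's first and last dispensation dates.
#' @param min_gap_days Minimum run length in days.
#' @return Tibble with `start_date`, `end_date` (day after the run, i.e. the
#'   re-initiation day), `duration_days`.
#' @export
uncovered_runs <- function(grid, first_date, last_date, min_gap_days = 91L) {
  inside <- grid$day >= first_date & grid$day < last_date
  unc <- inside & !grid$covered
  r <- rle(unc)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_gap_days
  tibble::tibble(
    start_date = grid$day[starts[keep]],
    end_date = grid$day[ends[keep]] + 1L,
    duration_days = as.integer(r$lengths[keep])
  )
}
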