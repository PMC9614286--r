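#' Configuration for the synthetic dispensation-data generator
#'
#' Defines the statistical structure of a simulated registry extract:
#' a four-region population observed over a fixed dispensation window, an
#' elderly age distribution, a depot LHRH drug mix dominated by leuprorelin,
#' triptorelin and goserelin, drug-specific refill schedules with Gaussian
#' jitter, a configurable fraction of patients with deliberate off-treatment
#' periods (log-normal durations, truncated), oral antiandrogen
#' co-dispensations, per-dispensation costs, and small contamination
#' fractions of under-age and antiandrogen-only subjects that exercise the
#' cohort filters.
#'
#' @param n_patients Number of simulated patients.
#' @param window_start,window_end Dispensation window (dates).
#' @param region_weights Named probabilities of region membership; default
#'   proportional to the four-community cohort sizes (Catalonia 0.5118,
#'   Madrid 0.3303, Basque Country 0.1079, Navarra 0.0500).
#' @param age_mean,age_sd,age_range Age (years) at window start: truncated
#'   normal, defaults 76.9, 10.4, truncated to \[40, 100\].
#' @param drug_weights Named probabilities of a patient's LHRH drug;
#'   defaults leuprorelin 0.5172, triptorelin 0.3472, goserelin 0.1233 with
#'   the remainder split between buserelin and histrelin.
#' @param p_intermittent Probability a patient follows an intermittent
#'   regimen (has at least one true off period); default 0.17.
#' @param off_median_months,off_sdlog,off_range_months Log-normal off-period
#'   duration law: median (months), log-scale SD, and truncation bounds;
#'   defaults median 6, sdlog 0.75, bounds \[3, 58\] months.  The lower
#'   bound must be at least the analysis minimum gap (`min_gap_days`).
#' @param refill_jitter_sd SD in days of the Gaussian jitter on regular
#'   refill dates (default 7); re-initiations after an off period are placed
#'   exactly at coverage end plus the drawn duration, so the realised
#'   uncovered run equals the drawn duration and ground truth is exact.
#' @param p_combination Probability, per covered month, of an oral
#'   antiandrogen co-dispensation (default 0.48).
#' @param cost_mean,cost_sd Euros per dispensation, normal truncated at 0
#'   (defaults 214, 32).
#' @param p_under18 Probability a patient is an under-age contaminant.
#' @param p_antiandrogen_only Probability a patient is dispensed
#'   antiandrogens only (castration not guaranteed; default 0.117).
#' @param corrupt_region_year Optional `c(region, year)`: 90% of that
#'   stratum's rows are dropped, emulating an incomplete electronic system
#'   (exercises the region-year QC path).
#' @param min_gap_days Analysis minimum gap the truth must respect.
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @return A validated list of class `adt_sim_config`.
#' @export
simulate_config <- function(n_patients = 1000L,
                            window_start = as.Date("2011-01-01"),
                            window_end = as.Date("2016-12-31"),
                            region_weights = c("Catalonia" = 0.51177,
                                               "Madrid" = 0.33030,
                                               "Basque Country" = 0.10790,
                                               "Navarra" = 0.05003),
                            age_mean = 76.9, age_sd = 10.4,
                            age_range = c(40, 100),
                            drug_weights = c(leuprorelin = 0.5172,
                                             triptorelin = 0.3472,
                                             goserelin = 0.1233,
                                             buserelin = 0.00615,
                                             histrelin = 0.00615),
                            p_intermittent = 0.17,
                            off_median_months = 6, off_sdlog = 0.75,
                            off_range_months = c(3, 58),
                            refill_jitter_sd = 7,
                            p_combination = 0.48,
                            cost_mean = 214, cost_sd = 32,
                            p_under18 = 0.005,
                            p_antiandrogen_only = 0.117,
                            corrupt_region_year = NULL,
                            min_gap_days = 91L,
                            seed = 1L) {
  window_start <- as.Date(window_start); window_end <- as.Date(window_end)
  if (!(window_start < window_end)) {
    stop_adt("config", "window_start must precede window_end")
  }
  probs <- c(p_intermittent, p_combination, p_under18, p_antiandrogen_only)
  if (any(probs < 0 | probs > 1)) {
    stop_adt("config", "probabilities must lie in [0, 1]")
  }
  for (w in list(region_weights = region_weights, drug_weights = drug_weights)) {
    if (any(w < 0) || abs(sum(w) - 1) > 1e-6) {
      stop_adt("config", "weights must be non-negative and sum to 1")
    }
  }
  if (p_under18 + p_antiandrogen_only > 1) {
    stop_adt("config", "contamination probabilities sum above 1")
  }
  dpm <- 30.44
  if (off_range_months[1] * dpm < min_gap_days) {
    stop_adt("config",
             "off-period truncation lower bound must be at least the minimum gap")
  }
  w_days <- as.integer(window_end - window_start)
  if (off_range_months[1] * dpm + 3 * 28 > w_days) {
    stop_adt("infeasible_simulation",
             "the shortest admissible off period cannot fit inside the window")
  }
  structure(list(
    n_patients = as.integer(n_patients),
    window_start = window_start, window_end = window_end,
    region_weights = region_weights,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    drug_weights = drug_weights,
    p_intermittent = p_intermittent,
    off_median_months = off_median_months, off_sdlog = off_sdlog,
    off_range_months = off_range_months,
    refill_jitter_sd = refill_jitter_sd,
    p_combination = p_combination,
    cost_mean = cost_mean, cost_sd = cost_sd,
    p_under18 = p_under18, p_antiandrogen_only = p_antiandrogen_only,
    corrupt_region_year = corrupt_region_year,
    min_gap_days = as.integer(min_gap_days),
    seed = as.integer(seed)
  ), class = "adt_sim_config")
}

## per-drug depot dose menus (mg) with sampling weights
depot_menu <- list(
  leuprorelin = list(dose = c(3.75, 11.25, 22.5), w = c(0.2, 0.5, 0.3)),
  triptorelin = list(dose = c(3.75, 11.25, 22.5), w = c(0.2, 0.5, 0.3)),
  goserelin = list(dose = 10.8, w = 1),
  buserelin = list(dose = 9.9, w = 1),
  histrelin = list(dose = 50, w = 1)
)

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    out[need] <- rnorm(length(need), mean, sd)
    need <- need[out[need] < lower | out[need] > upper]
  }
  out
}

draw_off_days <- function(config, max_total_days, n_off) {
  dpm <- 30.44
  lo <- config$off_range_months[1] * dpm
  hi <- config$off_range_months[2] * dpm
  meanlog <- log(config$off_median_months)
  for (i in 1:200) {
    m <- rlnorm(n_off, meanlog, config$off_sdlog)
    d <- round(m * dpm)
    d <- d[d >= ceiling(lo) - 0 & d >= ceiling(lo)]  # enforce lower bound
    m_ok <- length(d) == n_off && all(d <= floor(hi)) && sum(d) <= max_total_days
    if (m_ok) return(as.integer(d))
  }
  # fall back to the shortest admissible gap if the law keeps overshooting
  as.integer(rep(ceiling(lo), min(n_off, floor(max_total_days / ceiling(lo)))))
}

#' Generate a seeded synthetic dispensation cohort with ground truth
#'
#' Produces dispensation records shaped like a registry extract together
#' with the per-patient ground truth (regimen, true off periods,
#' contamination label) that the episode engine and prevalence estimators
#' can be validated against.  Intermittent patients receive off periods only
#' after at least two on-treatment dispensations and every off period is
#' followed by at least one further dispensation inside the window, so a
#' trailing gap never masquerades as intermittency.
#'
#' @param config An [simulate_config()] object.
#' @return A list of class `adt_cohort` with `records` (dispensation tibble
#'   in the canonical schema) and `truth`, itself a list of `patients`
#'   (`patient_id`, `regimen`, `excluded_reason`) and `off_periods`
#'   (`patient_id`, `start_date`, `end_date`, `duration_days`).
#' @examples
#' cohort <- simulate_cohort(simulate_config(n_patients = 50, seed = 7))
#' dplyr::count(cohort$truth$patients, regimen, excluded_reason)
#' @export
simulate_cohort <- function(config = simulate_config()) {
  stopifnot(inherits(config, "adt_sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  fmt <- adt_formulary()
  w0 <- as.integer(config$window_start)
  w1 <- as.integer(config$window_end)
  W <- w1 - w0

  n <- config$n_patients
  u <- runif(n)
  kind <- ifelse(u < config$p_under18, "under18",
                 ifelse(u < config$p_under18 + config$p_antiandrogen_only,
                        "antiandrogen_only", "included"))
  regions <- sample(names(config$region_weights), n, replace = TRUE,
                    prob = config$region_weights)
  ages <- rtruncnorm1(n, config$age_mean, config$age_sd,
                      config$age_range[1], config$age_range[2])
  drugs <- sample(names(config$drug_weights), n, replace = TRUE,
                  prob = config$drug_weights)
  iad <- runif(n) < config$p_intermittent

  rec_list <- vector("list", n)
  truth_off <- vector("list", n)
  regimen <- character(n)

  for (i in seq_len(n)) {
    pid <- sprintf("P%06d", i)
    if (kind[i] == "antiandrogen_only") {
      n_disp <- 6L + stats::rpois(1, 6)
      start <- w0 + floor(runif(1, 0, max(1, W - 30 * n_disp)))
      dates <- start + 30L * (seq_len(n_disp) - 1L)
      dates <- dates[dates <= w1]
      rec_list[[i]] <- list(patient_id = pid,
                            birth = w0 - round(ages[i] * 365.25),
                            region = regions[i], dates = dates,
                            drug = rep("bicalutamide", length(dates)),
                            atc = rep("L02BB03", length(dates)),
                            dose = rep(50, length(dates)))
      regimen[i] <- "CAD"
      next
    }

    drug <- drugs[i]
    menu <- depot_menu[[drug]]
    dose <- if (length(menu$dose) == 1) menu$dose else
      sample(menu$dose, 1, prob = menu$w)
    dur <- months_to_days(lookup_duration(fmt, drug, dose))

    if (kind[i] == "under18") {
      age_i <- runif(1, 5, 17)
      n_disp <- 2L + stats::rpois(1, 2)
      start <- w0 + floor(runif(1, 0, max(1, W - dur * n_disp)))
      dates <- start + dur * (seq_len(n_disp) - 1L)
      dates <- dates[dates <= w1]
      rec_list[[i]] <- list(patient_id = pid,
                            birth = start - round(age_i * 365.25),
                            region = regions[i], dates = dates,
                            drug = rep(drug, length(dates)),
                            atc = rep(atc_for(drug, fmt), length(dates)),
                            dose = rep(dose, length(dates)))
      regimen[i] <- "CAD"
      next
    }

    # included adult patient
    if (iad[i]) {
      n_off <- sample(1:2, 1, prob = c(0.7, 0.3))
      n_blocks <- n_off + 1L
      block_sizes <- c(2L + stats::rpois(1, 1), 1L + stats::rpois(n_blocks - 1L, 1))
      max_off_total <- W - (sum(block_sizes) - 1L) * dur
      if (max_off_total < ceiling(config$off_range_months[1] * 30.44)) {
        block_sizes <- c(2L, rep(1L, n_blocks - 1L))
        max_off_total <- W - (sum(block_sizes) - 1L) * dur
      }
      offs <- draw_off_days(config, max_off_total, n_off)
      n_off <- length(offs)
      if (n_off == 0) { iad[i] <- FALSE }
    }
    if (iad[i]) {
      span <- (sum(block_sizes) - 1L) * dur + sum(offs)
      start <- w0 + floor(runif(1, 0, max(1, W - span)))
      dates <- start
      cur <- start
      off_rec <- integer(0)
      for (b in seq_len(n_off + 1L)) {
        extra <- block_sizes[b] - 1L
        if (extra > 0) {
          for (k in seq_len(extra)) {
            step <- max(1, dur + round(rnorm(1, 0, config$refill_jitter_sd)))
            cur <- cur + step
            if (cur > w1) break
            dates <- c(dates, cur)
          }
        }
        if (b <= n_off) {
          nxt <- cur + dur + offs[b]
          if (nxt > w1) break
          off_rec <- c(off_rec, b)
          dates <- c(dates, nxt)
          cur <- nxt
        }
      }
      # persist on treatment until window end after the last re-initiation
      repeat {
        step <- max(1, dur + round(rnorm(1, 0, config$refill_jitter_sd)))
        if (cur + step > w1) break
        cur <- cur + step
        dates <- c(dates, cur)
      }
      # reconstruct realised off periods from the placed dates
      gaps <- diff(dates)
      big <- which(gaps - dur >= config$min_gap_days)
      if (length(big)) {
        truth_off[[i]] <- tibble::tibble(
          patient_id = pid,
          start_date = as.Date(dates[big] + dur, origin = "1970-01-01"),
          end_date = as.Date(dates[big + 1L], origin = "1970-01-01"),
          duration_days = as.integer(gaps[big] - dur)
        )
        regimen[i] <- "IAD"
      } else {
        regimen[i] <- "CAD"
      }
    } else {
      start <- w0 + floor(runif(1, 0, max(1, W - 2L * dur)))
      dates <- start
      cur <- start
      repeat {
        step <- max(1, dur + round(rnorm(1, 0, config$refill_jitter_sd)))
        if (cur + step > w1) break
        cur <- cur + step
        dates <- c(dates, cur)
      }
      regimen[i] <- "CAD"
    }

    drug_v <- rep(drug, length(dates))
    atc_v <- rep(atc_for(drug, fmt), length(dates))
    dose_v <- rep(dose, length(dates))

    # oral antiandrogen co-dispensations during covered months
    if (config$p_combination > 0) {
      mc <- max(1L, round(dur / 30.44))
      aa_dates <- integer(0)
      for (d in dates) {
        k <- rbinom(1, mc, config$p_combination)
        if (k > 0) {
          ms <- sample.int(mc, k)
          aa_dates <- c(aa_dates, d + 30L * (ms - 1L))
        }
      }
      aa_dates <- aa_dates[aa_dates <= w1]
      if (length(aa_dates)) {
        drug_v <- c(drug_v, rep("bicalutamide", length(aa_dates)))
        atc_v <- c(atc_v, rep("L02BB03", length(aa_dates)))
        dose_v <- c(dose_v, rep(50, length(aa_dates)))
        dates <- c(dates, aa_dates)
      }
    }

    rec_list[[i]] <- list(patient_id = pid,
                          birth = w0 - round(ages[i] * 365.25),
                          region = regions[i], dates = dates,
                          drug = drug_v, atc = atc_v, dose = dose_v)
  }

  lens <- vapply(rec_list, function(r) length(r$dates), integer(1))
  records <- tibble::tibble(
    patient_id = rep(vapply(rec_list, `[[`, character(1), "patient_id"), lens),
    birth_date = as.Date(rep(vapply(rec_list, `[[`, numeric(1), "birth"), lens),
                         origin = "1970-01-01"),
    region = rep(vapply(rec_list, `[[`, character(1), "region"), lens),
    dispense_date = as.Date(unlist(lapply(rec_list, `[[`, "dates")),
                            origin = "1970-01-01"),
    drug_name = unlist(lapply(rec_list, `[[`, "drug")),
    atc_code = unlist(lapply(rec_list, `[[`, "atc")),
    dose_mg = unlist(lapply(rec_list, `[[`, "dose")),
    n_units = 1L
  )
  records$cost_eur <- round(pmax(0, rnorm(nrow(records), config$cost_mean,
                                          config$cost_sd)), 2)

  if (!is.null(config$corrupt_region_year)) {
    reg <- config$corrupt_region_year[1]
    yr <- as.integer(config$corrupt_region_year[2])
    hit <- which(records$region == reg &
                   lubridate::year(records$dispense_date) == yr)
    drop <- sample(hit, size = floor(0.9 * length(hit)))
    if (length(drop)) records <- records[-drop, , drop = FALSE]
  }

  records <- dplyr::arrange(records, .data$patient_id, .data$dispense_date,
                            .data$atc_code)

  truth_patients <- tibble::tibble(
    patient_id = sprintf("P%06d", seq_len(n)),
    regimen = regimen,
    excluded_reason = ifelse(kind == "included", "none", kind)
  )
  off_tbl <- purrr::list_rbind(purrr::compact(truth_off))
  if (nrow(off_tbl) == 0) {
    off_tbl <- tibble::tibble(patient_id = character(),
                              start_date = as.Date(character()),
                              end_date = as.Date(character()),
                              duration_days = integer())
  }
  structure(list(records = records,
                 truth = list(patients = truth_patients, off_periods = off_tbl),
                 config = config),
            class = "adt_cohort")
}

atc_for <- function(drug, formulary) {
  formulary$atc_code[match(drug, formulary$drug_name)]
}

#' Write / read dispensation records as CSV
#'
#' The canonical on-disk format is a UTF-8 CSV with ISO-8601 dates and
#' columns `patient_id`, `birth_date`, `region`, `dispense_date`,
#' `drug_name`, `atc_code`, `dose_mg`, `n_units`, `cost_eur`.  The reader
#' validates the schema and reports row-level violations (missing ids,
#' unparseable dates, non-positive doses or units, negative costs) with
#' their line numbers.
#'
#' @param records Dispensation tibble.
#' @param path File path.
#' @return `write_records()` returns `path` invisibly; `read_records()`
#'   returns the validated tibble.
#' @export
write_records <- function(records, path) {
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

record_cols <- c("patient_id", "birth_date", "region", "dispense_date",
                 "drug_name", "atc_code", "dose_mg", "n_units", "cost_eur")

#' @rdname write_records
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop_adt("io", sprintf("file not found: %s", path))
  out <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    birth_date = readr::col_date(),
    region = readr::col_character(),
    dispense_date = readr::col_date(),
    drug_name = readr::col_character(),
    atc_code = readr::col_character(),
    dose_mg = readr::col_double(),
    n_units = readr::col_integer(),
    cost_eur = readr::col_double()
  ), progress = FALSE, show_col_types = FALSE))
  missing <- setdiff(record_cols, names(out))
  if (length(missing)) {
    stop_adt("schema", sprintf("missing required columns: %s",
                               paste(missing, collapse = ", ")),
             missing = missing)
  }
  prob <- readr::problems(out)
  bad <- is.na(out$patient_id) | is.na(out$birth_date) |
    is.na(out$dispense_date) | is.na(out$dose_mg) | out$dose_mg <= 0 |
    is.na(out$n_units) | out$n_units < 1 | is.na(out$cost_eur) | out$cost_eur < 0
  lines <- sort(unique(c(which(bad) + 1L, prob$row + 1L)))
  if (length(lines)) {
    stop_adt("schema",
             sprintf("invalid rows at lines: %s",
                     paste(head(lines, 10), collapse = ", ")),
             lines = lines)
  }
  out[record_cols]
}
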