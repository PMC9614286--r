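# seeded synthetic dispensation generator and its ground truth

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- simulate_config(n_patients = 100, seed = 31)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
})

test_that("jitterless continuous refills leave no uncovered day", {
  cfg <- simulate_config(n_patients = 80, p_intermittent = 0,
                         refill_jitter_sd = 0, p_under18 = 0,
                         p_antiandrogen_only = 0, seed = 32)
  co <- simulate_cohort(cfg)
  ep <- build_episodes(co$records, FMT)
  expect_true(all(ep$intervals$uncovered_days == 0))
})

test_that("jitterless true off periods equal the day-grid uncovered runs", {
  cfg <- simulate_config(n_patients = 60, p_intermittent = 0.5,
                         refill_jitter_sd = 0, p_under18 = 0,
                         p_antiandrogen_only = 0, seed = 33)
  co <- simulate_cohort(cfg)
  ep <- build_episodes(co$records, FMT)
  truth <- dplyr::arrange(co$truth$off_periods, patient_id, start_date)
  det <- dplyr::arrange(ep$off_periods, patient_id, start_date)
  expect_equal(det$patient_id, truth$patient_id)
  expect_equal(det$start_date, truth$start_date)
  expect_equal(det$duration_days, truth$duration_days)
  # spot-check a couple against the brute-force grid
  ids <- unique(truth$patient_id)[1:2]
  for (pid in ids) {
    r <- co$records[co$records$patient_id == pid, ]
    grid <- day_grid_oracle(r, FMT, c(cfg$window_start, cfg$window_end))
    runs <- uncovered_runs(grid, min(r$dispense_date), max(r$dispense_date), 91L)
    expect_equal(runs$duration_days,
                 truth$duration_days[truth$patient_id == pid])
  }
})

test_that("ground truth is internally consistent", {
  co <- shared_cohort_5000()
  tr <- co$truth
  iad <- tr$patients$patient_id[tr$patients$regimen == "IAD"]
  expect_setequal(unique(tr$off_periods$patient_id), iad)
  expect_true(all(tr$off_periods$duration_days >= 91))
  expect_true(all(tr$off_periods$end_date > tr$off_periods$start_date))
  # off periods only for included patients
  contaminated <- tr$patients$patient_id[tr$patients$excluded_reason != "none"]
  expect_length(intersect(tr$off_periods$patient_id, contaminated), 0)
})

test_that("the simulated cohort matches its configured moments", {
  co <- shared_cohort_5000()
  cfg <- co$config
  included <- co$truth$patients$patient_id[co$truth$patients$excluded_reason == "none"]
  first <- co$records %>%
    dplyr::filter(patient_id %in% included) %>%
    dplyr::group_by(patient_id) %>%
    dplyr::summarise(birth = dplyr::first(birth_date), .groups = "drop")
  age <- as.numeric(cfg$window_start - first$birth) / 365.25
  se <- cfg$age_sd / sqrt(length(age))
  expect_lt(abs(mean(age) - cfg$age_mean), 3 * se + 0.5)  # truncation shifts slightly

  lhrh <- co$records %>%
    dplyr::filter(classify_drug(atc_code) == "lhrh_analogue",
                  patient_id %in% included) %>%
    dplyr::distinct(patient_id, drug_name)
  shares <- table(lhrh$drug_name) / nrow(lhrh)
  for (d in c("leuprorelin", "triptorelin", "goserelin")) {
    p <- cfg$drug_weights[[d]]
    expect_lt(abs(shares[[d]] - p), 3 * sqrt(p * (1 - p) / nrow(lhrh)))
  }

  months <- co$truth$off_periods$duration_days / 30.44
  expect_true(all(months >= cfg$off_range_months[1] - 0.02))
  expect_true(all(months <= cfg$off_range_months[2] + 0.02))

  cost <- co$records$cost_eur
  expect_lt(abs(mean(cost) - cfg$cost_mean),
            3 * cfg$cost_sd / sqrt(length(cost)))
})

test_that("records survive a write/read round trip", {
  co <- simulate_cohort(simulate_config(n_patients = 40, seed = 35))
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(co$records, path)
  back <- read_records(path)
  expect_equal(back, co$records)
})

test_that("the reader rejects malformed files with line numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  co <- simulate_cohort(simulate_config(n_patients = 5, seed = 36))
  # missing dose column
  readr::write_csv(dplyr::select(co$records, -dose_mg), path)
  expect_error(read_records(path), class = "adtgaps_error_schema")
  # negative cost on one row
  bad <- co$records
  bad$cost_eur[3] <- -5
  readr::write_csv(bad, path)
  cond <- tryCatch(read_records(path), condition = function(c) c)
  expect_s3_class(cond, "adtgaps_error_schema")
  expect_true(4 %in% cond$lines)  # row 3 + header line
  # empty file with a valid header parses to zero rows
  readr::write_csv(co$records[0, ], path)
  expect_equal(nrow(read_records(path)), 0)
  expect_error(read_records(file.path(tempdir(), "absent.csv")),
               class = "adtgaps_error_io")
})

test_that("invalid configurations are refused up front", {
  expect_error(simulate_config(region_weights = c(A = 0.5, B = 0.6)),
               class = "adtgaps_error_config")
  expect_error(simulate_config(p_intermittent = 1.2),
               class = "adtgaps_error_config")
  expect_error(simulate_config(window_start = "2016-01-01",
                               window_end = "2011-01-01"),
               class = "adtgaps_error_config")
  # off periods shorter than the minimum gap would break truth alignment
  expect_error(simulate_config(off_range_months = c(1, 58)),
               class = "adtgaps_error_config")
  # off period that cannot fit inside the window at all
  expect_error(simulate_config(window_start = "2011-01-01",
                               window_end = "2011-06-30",
                               off_range_months = c(6, 12)),
               class = "adtgaps_error_infeasible_simulation")
})

test_that("a corrupted region-year loses most of its rows and is QC-flagged", {
  cfg <- simulate_config(n_patients = 400, seed = 37,
                         corrupt_region_year = c("Catalonia", "2013"))
  co <- simulate_cohort(cfg)
  counts <- co$records %>%
    dplyr::filter(region == "Catalonia") %>%
    dplyr::count(year = lubridate::year(dispense_date))
  y2013 <- counts$n[counts$year == 2013]
  other <- median(counts$n[counts$year %in% 2012:2016 & counts$year != 2013])
  expect_lt(y2013, 0.5 * other)
  flags <- qc_region_years(co$records)
  expect_true(any(flags$region == "Catalonia" & flags$year == 2013))
})
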