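# prevalence estimators, off-period summaries and supporting statistics

# small deterministic cohort: ten adults observed from 2011, two of them with
# a single off period that falls in 2012 (coverage of the day-300 depot ends
# at day 391 = 2012-01-27; re-initiation 120 or 200 days later)
mini_cohort <- function() {
  origin <- as.Date("2011-01-01")
  ids <- sprintf("M%02d", 1:10)
  cad <- purrr::list_rbind(purrr::map(ids[1:8], function(p) {
    history(seq(0, 1500, by = 85), patient_id = p, origin = origin)
  }))
  on_block <- c(0, 85, 170, 255, 300)
  iad1 <- history(c(on_block, 391 + 120, 391 + 120 + 85), patient_id = "M09",
                  origin = origin)
  iad2 <- history(c(on_block, 391 + 200, 391 + 200 + 85), patient_id = "M10",
                  origin = origin)
  dplyr::bind_rows(cad, iad1, iad2)
}

test_that("Wilson interval hits its closed form and boundary behaviour", {
  expect_equal(wilson_ci(0, 100)$low, 0)
  expect_equal(wilson_ci(100, 100)$high, 1)
  # independent evaluation of the textbook formula for k = 10, n = 100
  z <- qnorm(0.975)
  p <- 0.1; n <- 100
  lo <- (p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
  hi <- (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
  ci <- wilson_ci(10, 100)
  expect_equal(ci$low, lo, tolerance = 1e-12)
  expect_equal(ci$high, hi, tolerance = 1e-12)
  expect_error(wilson_ci(1, 0), class = "adtgaps_error_undefined_prevalence")
  expect_error(wilson_ci(5, 3), class = "adtgaps_error_config")
})

test_that("coverage, not dispensation dates, decides treated-in-year membership", {
  # a 6-month depot dispensed 2013-12-01 covers into 2014
  ep <- build_episodes(disp(day = 0, dose = 22.5,
                            origin = as.Date("2013-12-01")), FMT)
  expect_equal(treated_in_year(ep, 2013), "P1")
  expect_equal(treated_in_year(ep, 2014), "P1")
  expect_warning(treated_in_year(ep, 2016),
                 class = "adtgaps_warning_empty_stratum")
  # coverage ending exactly with the year (half-open): treated in 2014 only
  ep2 <- build_episodes(disp(day = 0, dose = 3.75,  # 30 days
                             origin = as.Date("2014-12-02")), FMT)
  expect_equal(treated_in_year(ep2, 2014), "P1")
  expect_length(suppressWarnings(treated_in_year(ep2, 2015)), 0)
})

test_that("annual prevalence is the intermittent share of treated patients", {
  ep <- build_episodes(mini_cohort(), FMT)
  est <- annual_p_iad(ep, 2012)
  expect_equal(est$n_treated, 10L)
  expect_equal(est$n_intermittent, 2L)
  expect_equal(est$p_iad, 0.2)
  expect_true(est$ci_low <= est$p_iad && est$p_iad <= est$ci_high)
  # a cohort with no off periods has zero prevalence in every year
  cad_only <- dplyr::filter(mini_cohort(), !patient_id %in% c("M09", "M10"))
  cad <- build_episodes(cad_only, FMT)
  expect_equal(annual_p_iad(cad, 2013)$p_iad, 0)
  # the first observed year is refused without the override
  expect_error(annual_p_iad(ep, 2011), class = "adtgaps_error_first_year")
  expect_error(annual_p_iad(build_episodes(mini_cohort(), FMT), 2012,
                            region = "Madrid"),
               class = "adtgaps_error_undefined_prevalence")
})

test_that("the first-year refusal is the first *observed* year", {
  ep <- build_episodes(mini_cohort(), FMT)
  expect_error(annual_p_iad(ep, 2011), class = "adtgaps_error_first_year")
  est <- annual_p_iad(ep, 2011, include_first_year = TRUE)
  expect_true(est$underestimated)
  expect_false(annual_p_iad(ep, 2012)$underestimated)
})

test_that("global prevalence counts ever-intermittent patients", {
  ep <- build_episodes(mini_cohort(), FMT)
  g <- global_p_iad(ep)
  expect_equal(g$n_treated, 10L)
  expect_equal(g$n_intermittent, 2L)
  expect_equal(g$p_iad, 0.2)
  # the printed-share arithmetic: 7,489 of 44,264 rounds to 17%
  expect_equal(round(100 * 7489 / 44264), 17)
  # degenerate cohorts
  iad_only <- dplyr::filter(mini_cohort(), patient_id %in% c("M09", "M10"))
  expect_equal(global_p_iad(build_episodes(iad_only, FMT))$p_iad, 1)
})

test_that("mean annual prevalence averages yearly values unweighted", {
  expect_equal(mean_annual_p_iad(c(0.05, 0.05, 0.05)), 0.05)
  expect_equal(mean_annual_p_iad(c(0, 0.5)), 0.25)
  ep <- build_episodes(mini_cohort(), FMT)
  vals <- purrr::map_dbl(2013:2015, ~ annual_p_iad(ep, .x)$p_iad)
  expect_equal(mean_annual_p_iad(ep, years = 2013:2015), mean(vals))
})

test_that("percent time off treatment honours the denominator scope", {
  # one patient, span 365, one 100-day off period
  one <- build_episodes(history(c(0, 191, 365), patient_id = "X1"), FMT)
  expect_equal(percent_iad(one)$percent_iad, 100 / 365)
  # add a fully adherent patient with the same span
  two <- build_episodes(dplyr::bind_rows(
    history(c(0, 191, 365), patient_id = "X1"),
    history(seq(0, 365, by = 85), patient_id = "X2")
  ), FMT)
  expect_equal(percent_iad(two, scope = "all_patients")$percent_iad,
               100 / (365 + 340))
  expect_equal(percent_iad(two, scope = "iad_patients_only")$percent_iad,
               100 / 365)
  # no off periods anywhere -> zero
  cad <- build_episodes(history(c(0, 85), patient_id = "X3"), FMT)
  expect_equal(percent_iad(cad)$percent_iad, 0)
  single <- build_episodes(history(0, patient_id = "X4"), FMT)
  expect_error(percent_iad(single), class = "adtgaps_error_undefined_percent")
})

test_that("off-period summaries use interpolated quantiles in months", {
  mk_ep <- function(durs) {
    recs <- purrr::list_rbind(purrr::imap(durs, function(d, i) {
      history(c(0, 91 + d, 91 + d + 85), patient_id = sprintf("Q%02d", i))
    }))
    build_episodes(recs, FMT)
  }
  s <- offperiod_summary(mk_ep(c(91, 183, 365)))
  expect_equal(s$median_months, 183 / 30.44)
  expect_equal(s$n_off_periods, 3L)
  s1 <- offperiod_summary(mk_ep(120))
  expect_equal(s1$iqr_months, 0)
  # hand-computed type-7 quartiles of 120, 150, 180, 400 days
  s4 <- offperiod_summary(mk_ep(c(120, 150, 180, 400)))
  expect_equal(s4$median_months, 165 / 30.44)
  expect_equal(s4$iqr_months, (235 - 142.5) / 30.44)
  expect_equal(s4$min_months, 120 / 30.44)
  expect_equal(s4$max_months, 400 / 30.44)
  expect_warning(offperiod_summary(mk_ep(120), region = "Madrid"),
                 class = "adtgaps_warning_empty_stratum")
})

test_that("chi-square matches the 2x2 closed form and degenerate rules", {
  expect_equal(chi_square_independence(rbind(c(10, 90), c(20, 180)))$statistic, 0)
  expect_equal(chi_square_independence(rbind(c(10, 90), c(20, 180)))$p_value, 1)
  withr::with_seed(21, {
    for (i in 1:20) {
      a <- sample(1:50, 1); b <- sample(1:50, 1)
      c <- sample(1:50, 1); d <- sample(1:50, 1)
      n <- a + b + c + d
      closed <- n * (a * d - b * c)^2 /
        ((a + b) * (c + d) * (a + c) * (b + d))
      got <- chi_square_independence(rbind(c(a, b), c(c, d)))
      expect_equal(got$statistic, closed, tolerance = 1e-10)
      expect_equal(got$df, 1)
      expect_equal(got$p_value, pchisq(closed, 1, lower.tail = FALSE))
    }
  })
  extreme <- chi_square_independence(rbind(c(50, 0), c(0, 50)))
  expect_lt(extreme$p_value, 1e-4)
  expect_error(chi_square_independence(rbind(c(0, 0), c(5, 5))),
               class = "adtgaps_error_degenerate_table")
  expect_error(chi_square_independence(matrix(1:3, 1)),
               class = "adtgaps_error_degenerate_table")
})

test_that("regional strata add up to the pooled counts", {
  co <- simulate_cohort(simulate_config(n_patients = 800, seed = 44))
  res <- adt_run(co$records)
  prev <- res$prevalence
  for (y in unique(prev$year)) {
    pooled <- prev[prev$year == y & prev$region == "all", ]
    strata <- prev[prev$year == y & prev$region != "all", ]
    expect_equal(sum(strata$n_intermittent), pooled$n_intermittent)
    expect_equal(sum(strata$n_treated), pooled$n_treated)
  }
  expect_true(all(prev$p_iad >= 0 & prev$p_iad <= 1))
  expect_true(all(prev$ci_low <= prev$p_iad & prev$p_iad <= prev$ci_high))
  # global prevalence equals the pooled ever-intermittent fraction by definition
  ep <- res$episodes
  expect_equal(res$global_prevalence$p_iad,
               dplyr::n_distinct(ep$off_periods$patient_id) / nrow(ep$patients))
})
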