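# shared fixture builders for the suite

suppressPackageStartupMessages(library(dplyr))

FMT <- adt_formulary()

# one dispensation row; dates given as offsets from an origin for readability
disp <- function(patient_id = "P1", day = 0, drug = "leuprorelin",
                 dose = 11.25, atc = "L02AE02", n_units = 1L,
                 cost = 200, origin = as.Date("2012-01-01"),
                 birth = as.Date("1940-06-15"), region = "Catalonia") {
  tibble::tibble(
    patient_id = patient_id, birth_date = birth, region = region,
    dispense_date = origin + day, drug_name = drug, atc_code = atc,
    dose_mg = dose, n_units = as.integer(n_units), cost_eur = cost
  )
}

# a patient history from day offsets (3-month depot by default)
history <- function(days, patient_id = "P1", drug = "leuprorelin",
                    dose = 11.25, atc = "L02AE02", n_units = 1L, ...) {
  purrr::list_rbind(purrr::map(days, function(d) {
    disp(patient_id = patient_id, day = d, drug = drug, dose = dose,
         atc = atc, n_units = n_units, ...)
  }))
}

# random patient histories for fuzzing against the day-grid oracle
fuzz_history <- function(patient_id, origin = as.Date("2011-01-01")) {
  menu <- list(
    list(drug = "leuprorelin", atc = "L02AE02", dose = c(3.75, 11.25, 22.5)),
    list(drug = "triptorelin", atc = "L02AE04", dose = c(3.75, 11.25, 22.5)),
    list(drug = "goserelin", atc = "L02AE03", dose = 10.8),
    list(drug = "histrelin", atc = "H01CA03", dose = c(3.6, 50))
  )
  n <- sample(1:10, 1)
  days <- sort(sample(0:1500, n))
  rows <- purrr::map(days, function(d) {
    m <- menu[[sample(length(menu), 1)]]
    disp(patient_id = patient_id, day = d, drug = m$drug, atc = m$atc,
         dose = if (length(m$dose) > 1) sample(m$dose, 1) else m$dose,
         n_units = sample(1:2, 1, prob = c(0.9, 0.1)), origin = origin)
  })
  purrr::list_rbind(rows)
}

# cache one large cohort shared by the distributional tests
.fixture_cache <- new.env(parent = emptyenv())
shared_cohort_5000 <- function() {
  if (is.null(.fixture_cache$c5000)) {
    .fixture_cache$c5000 <- simulate_cohort(simulate_config(n_patients = 5000,
                                                            seed = 424242))
  }
  .fixture_cache$c5000
}
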