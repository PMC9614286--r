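#' Load the LHRH analogue / antiandrogen formulary
#'
#' The formulary maps each commercially available depot formulation
#' (drug, dose in mg) to its nominal duration of action and drug class.
#' Dose entries are stored as closed bands `[dose_mg_low, dose_mg_high]`;
#' most bands are degenerate (a single dose), while daily formulations sold
#' at doses up to 2 mg share one band.  Daily formulations carry a
#' fractional `duration_months` equal to one day under the default
#' days-per-month policy, so a single dispensed unit covers one day.
#'
#' @param path Optional path to a tab-separated formulary file with columns
#'   `drug_name`, `atc_code`, `dose_mg_low`, `dose_mg_high`,
#'   `duration_months`, `drug_class`; defaults to the formulary bundled
#'   with the package.
#' @param aliases_path Optional path to a two-column (`alias`, `canonical`)
#'   tab-separated table of drug-name spelling variants; defaults to the
#'   bundled Spanish/English alias table.
#'
#' @return A tibble of class `adt_formulary`, one row per (drug, dose band),
#'   with the alias table attached as attribute `aliases`.
#' @examples
#' fmt <- adt_formulary()
#' lookup_duration(fmt, "leuprorelin", 22.5)
#' @export
adt_formulary <- function(path = NULL, aliases_path = NULL) {
  path <- path %||%
    system.file("extdata", "formulary.tsv", package = "adtgaps", mustWork = TRUE)
  aliases_path <- aliases_path %||%
    system.file("extdata", "drug_aliases.tsv", package = "adtgaps", mustWork = TRUE)
  fmt <- readr::read_tsv(path, col_types = readr::cols(
    drug_name = readr::col_character(),
    atc_code = readr::col_character(),
    dose_mg_low = readr::col_double(),
    dose_mg_high = readr::col_double(),
    duration_months = readr::col_double(),
    drug_class = readr::col_character()
  ), progress = FALSE)
  aliases <- readr::read_tsv(aliases_path, col_types = readr::cols(
    alias = readr::col_character(), canonical = readr::col_character()
  ), progress = FALSE)
  if (any(fmt$duration_months <= 0)) {
    stop_adt("config", "formulary durations must be strictly positive")
  }
  if (any(fmt$dose_mg_low > fmt$dose_mg_high)) {
    stop_adt("config", "formulary dose bands must satisfy dose_mg_low <= dose_mg_high")
  }
  if (anyDuplicated(fmt[c("drug_name", "dose_mg_low", "dose_mg_high")])) {
    stop_adt("config", "formulary (drug, dose band) entries must be unique")
  }
  attr(fmt, "aliases") <- aliases
  class(fmt) <- c("adt_formulary", class(fmt))
  fmt
}

#' Canonicalise drug names
#'
#' Lower-cases, trims, strips diacritics and resolves spelling variants
#' (e.g. "Leuproreline", "triptorelina") to the canonical formulary name.
#'
#' @param x Character vector of drug names.
#' @param formulary An [adt_formulary()] (source of the alias table).
#' @return Character vector of canonical names.
#' @export
canonical_drug_name <- function(x, formulary = adt_formulary()) {
  aliases <- attr(formulary, "aliases")
  out <- tolower(trimws(as.character(x)))
  out <- iconv(out, from = "UTF-8", to = "ASCII//TRANSLIT")
  hit <- match(out, aliases$alias)
  out[!is.na(hit)] <- aliases$canonical[hit[!is.na(hit)]]
  out
}

## internal: match (drug, dose) pairs to formulary rows; NA where no dose row
match_formulary <- function(formulary, drug_name, dose_mg) {
  drug <- canonical_drug_name(drug_name, formulary)
  idx <- integer(length(drug))
  known <- drug %in% formulary$drug_name
  idx[!known] <- NA_integer_
  for (i in which(known)) {
    rows <- which(formulary$drug_name == drug[i] &
                    formulary$dose_mg_low - 1e-9 <= dose_mg[i] &
                    dose_mg[i] <= formulary$dose_mg_high + 1e-9)
    idx[i] <- if (length(rows)) rows[1] else -1L
  }
  list(idx = idx, drug = drug, known = known)
}

#' Look up the nominal duration of action for a (drug, dose) pair
#'
#' @param formulary An [adt_formulary()].
#' @param drug_name Character vector of drug names (spelling variants accepted).
#' @param dose_mg Numeric vector of doses in mg (recycled against `drug_name`).
#' @return Numeric vector of nominal durations in months (daily formulations
#'   return the fractional month equivalent of one day).
#' @section Errors: signals `adtgaps_error_unknown_drug` for a drug absent
#'   from the formulary and `adtgaps_error_unknown_dose` for a known drug at
#'   an unlisted dose; both conditions carry `drug_name` and `dose_mg` fields.
#' @examples
#' fmt <- adt_formulary()
#' lookup_duration(fmt, c("leuprorelin", "goserelin"), c(22.5, 10.8))
#' @export
lookup_duration <- function(formulary, drug_name, dose_mg) {
  n <- max(length(drug_name), length(dose_mg))
  drug_name <- rep_len(drug_name, n)
  dose_mg <- rep_len(dose_mg, n)
  m <- match_formulary(formulary, drug_name, dose_mg)
  if (any(!m$known)) {
    i <- which(!m$known)[1]
    stop_adt("unknown_drug",
             sprintf("drug not in formulary: '%s' (dose %g mg)", drug_name[i], dose_mg[i]),
             drug_name = drug_name[i], dose_mg = dose_mg[i])
  }
  if (any(m$idx < 0, na.rm = TRUE)) {
    i <- which(m$idx < 0)[1]
    stop_adt("unknown_dose",
             sprintf("dose not listed for '%s': %g mg", m$drug[i], dose_mg[i]),
             drug_name = m$drug[i], dose_mg = dose_mg[i])
  }
  formulary$duration_months[m$idx]
}

#' Classify an ATC code as LHRH analogue or antiandrogen
#'
#' LHRH analogue families are `L02AE*` (gonadotropin-releasing hormone
#' analogues) and `H01CA*`; antiandrogens are `L02BB*`.
#'
#' @param atc_code Character vector of ATC codes.
#' @return Character vector with values `"lhrh_analogue"` or `"antiandrogen"`.
#' @section Errors: a non-empty code outside both families signals
#'   `adtgaps_error_unclassified_drug` carrying `atc_code`.
#' @examples
#' classify_drug(c("L02AE02", "L02BB03"))
#' @export
classify_drug <- function(atc_code) {
  atc_code <- toupper(trimws(as.character(atc_code)))
  if (length(atc_code) == 0) return(character(0))
  if (any(is.na(atc_code) | atc_code == "")) {
    stop_adt("unclassified_drug", "empty ATC code")
  }
  out <- rep(NA_character_, length(atc_code))
  out[startsWith(atc_code, "L02AE") | startsWith(atc_code, "H01CA")] <- "lhrh_analogue"
  out[startsWith(atc_code, "L02BB")] <- "antiandrogen"
  if (anyNA(out)) {
    bad <- atc_code[which(is.na(out))[1]]
    stop_adt("unclassified_drug",
             sprintf("ATC code outside the LHRH/antiandrogen families: '%s'", bad),
             atc_code = bad)
  }
  out
}

#' Month-to-day conversion policy
#'
#' @param days_per_month Days per nominal month; default 30.44 (365.25 / 12).
#'   Must lie in \[28, 31\].
#' @return A list of class `adt_duration_policy`.
#' @export
duration_policy <- function(days_per_month = 30.44) {
  if (!is.numeric(days_per_month) || length(days_per_month) != 1 ||
      days_per_month < 28 || days_per_month > 31) {
    stop_adt("config", "days_per_month must be a single number in [28, 31]")
  }
  structure(list(days_per_month = days_per_month, rounding = "nearest_day"),
            class = "adt_duration_policy")
}

#' Convert nominal month durations to whole days
#'
#' Multiplies by the policy's days-per-month and rounds to the nearest whole
#' day (half-days round up).  Under the default policy 1 month is 30 days,
#' 2 months 61, 3 months 91, 6 months 183 and 12 months 365.
#'
#' @param duration_months Non-negative numeric vector.
#' @param policy A [duration_policy()].
#' @return Integer vector of days.
#' @examples
#' months_to_days(c(1, 3, 6, 12))
#' @export
months_to_days <- function(duration_months, policy = duration_policy()) {
  if (any(is.na(duration_months)) || any(duration_months < 0)) {
    stop_adt("invalid_duration", "durations must be non-negative and non-missing")
  }
  as.integer(floor(duration_months * policy$days_per_month + 0.5))
}
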