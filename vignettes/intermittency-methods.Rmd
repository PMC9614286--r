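---
title: "Reconstructing intermittent androgen deprivation from dispensation records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing intermittent androgen deprivation from dispensation records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adtgaps)
library(dplyr)
```

## The problem

Androgen deprivation therapy (ADT) for prostate cancer is usually delivered
as depot injections of LHRH analogues that suppress testosterone for a
drug- and dose-specific period — one, two, three, six or twelve nominal
months. Intermittent androgen deprivation (IAD) deliberately alternates
on-treatment blocks with off-treatment pauses; continuous deprivation (CAD)
does not. Pharmacy dispensation registries record *when* each depot was
dispensed but not the clinician's intent, so intermittency has to be
reconstructed from the timing of refills.

`adtgaps` implements that reconstruction as a pipeline:

1. **Formulary** — map each dispensed (drug, dose) pair to its nominal
   duration of action, and classify ATC codes into LHRH analogues
   (`L02AE*`, `H01CA*`) versus oral antiandrogens (`L02BB*`).
2. **Cohort filters** — drop patients under 18 at first dispensation
   (likely precocious-puberty indications), patients dispensed
   antiandrogens only (castration not guaranteed), and explicitly
   configured (region, year) strata with incomplete data.
3. **Episode engine** — per patient, build interval times (IntT) between
   consecutive LHRH dispensations, track the effect of the last dose (ELD),
   and flag uncovered runs of at least a minimum gap that end in a
   confirmed re-initiation: potentially intermittent interval times (PIIT).
4. **Prevalence metrics** — annual and global prevalence of intermittency
   (P_IAD) with Wilson intervals, the percentage of time off treatment
   (%IAD), off-period duration summaries, and chi-square comparisons.
5. **Cost accounting** — expenditure per drug/class/year/region,
   normalised as euros per dispensation.

## The episode model

For one patient with LHRH dispensations at dates $t_1 < t_2 < \dots < t_n$,
each dispensation confers coverage for $e_i$ days (the formulary duration
converted to days, times the number of dispensed units). Same-day rows are
merged with units summed. With carry-forward (the default), coverage ends at

$$c_i = \max(c_{i-1},\; t_i + e_i),$$

so an early refill stockpiles unexpired coverage rather than forfeiting it.
The uncovered days of interval $i$ are $u_i = \max(0, t_{i+1} - c_i)$, and
an interval is a PIIT when $u_i \ge g$, the minimum gap. The off period is
anchored at the day coverage ends ($c_i$) and terminates at $t_{i+1}$ — a
**confirmed re-initiation**. The open-ended gap after $t_n$ is never an off
period: a stop without restart (death, progression, true discontinuation)
is not intermittency. This makes the estimate conservative by construction.

Because $c_i$ is a running maximum, the union of per-dose coverage windows
$[t_i, t_i + e_i)$ equals the union of $[t_i, c_i)$; the package exploits
this equivalence in `day_grid_oracle()`, a brute-force per-day coverage
oracle used by the test-suite to cross-check the interval arithmetic on
thousands of fuzzed histories.

### Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `min_gap_days` | 91 | days | three nominal months; an intermittency pause normally follows at least six months of treatment, so three months is a deliberately conservative detection floor |
| `carry_forward` | `TRUE` | — | stockpiling minimises false off periods; switchable for sensitivity analysis |
| `days_per_month` | 30.44 | days | 365.25/12, calendar-faithful; gives 1 m → 30 d, 3 m → 91 d, 6 m → 183 d, 12 m → 365 d |
| `conf` | 0.95 | — | Wilson score interval; well-behaved near 0 where annual prevalences live |

The formulary ships as a plain TSV (`inst/extdata/formulary.tsv`) so a user
can override it; dose entries are closed bands, with the daily formulations
(doses up to 2 mg) carrying a fractional month duration that converts to
exactly one day per dispensed unit.

## Estimators

**Annual P_IAD.** A patient counts in the numerator of year $Y$ iff at
least one off-period day falls in $Y$ (overlap rule — a pause spanning a
year boundary counts in both years). The denominator is every patient with
at least one day of LHRH *coverage* in $Y$, so a six-month depot dispensed
in December contributes to the next year's denominator too. The first
observed calendar year is refused by default: a patient already pausing
when observation starts cannot be recognised as intermittent, so that
year's prevalence is structurally underestimated; `include_first_year =
TRUE` overrides and flags the estimate.

**Global P_IAD.** The ever-intermittent share over the whole window. This
deliberately overstates annual prevalence — a patient intermittent in one
year counts for the whole period — which is why the package reports the
unweighted mean of the annual values (`mean_annual_p_iad()`) as the
headline figure.

**%IAD.** Total off-period days divided by the total days between each
patient's first and last dispensation. The denominator defaults to *all*
included patients: with that convention the %IAD and the mean annual P_IAD
land on the same order of magnitude, which is the internal-consistency
check the pipeline reports; restricting the denominator to intermittent
patients is available as `denominator_scope = "iad_patients_only"`.

**Off-period summaries** use type-7 (linearly interpolated) quantiles on
durations converted to months; a stated convention beats an unstated one.
**Chi-square** comparisons of intermittency across regions or years use the
Pearson statistic without continuity correction (large-sample registry
setting); Yates correction is a flag.

## The synthetic cohort generator

`simulate_cohort()` generates registry-shaped dispensation data with known
ground truth, used throughout the tests for parameter recovery. Its
defaults encode the study conditions the package targets:

* four regions with weights 0.512/0.330/0.108/0.050
  (Catalonia/Madrid/Basque Country/Navarra), window 2011-01-01 to
  2016-12-31;
* age at window start truncated-normal, mean 76.9, SD 10.4, range 40–100;
* drug mix leuprorelin 51.72%, triptorelin 34.72%, goserelin 12.33%, the
  remainder split between buserelin and histrelin; within
  leuprorelin/triptorelin the depot dose is drawn as 1-month 20%, 3-month
  50%, 6-month 30% — a plausible mix the sources do not pin down;
* `p_intermittent = 0.17`, the ever-intermittent share of the study
  window; off-period durations log-normal with median 6 months
  (`sdlog = 0.75`), truncated to [3, 58] months;
* refill jitter Gaussian with SD 7 days; per-dispensation cost normal
  (mean 214 €, SD 32 €, truncated at 0); antiandrogen co-dispensation
  probability 0.48 per covered month, which reproduces the roughly 1.4:1
  ratio of antiandrogen to LHRH dispensation counts;
* contamination: 0.5% under-age patients and 11.7% antiandrogen-only
  patients, matching the exclusion-flowchart proportions.

Two construction rules keep the ground truth exactly recoverable. Off
periods are inserted only after at least two on-treatment dispensations and
are always followed by a re-initiation inside the window, so a trailing gap
never masquerades as intermittency. And the re-initiation after an off
period is placed exactly at coverage-end plus the drawn duration (no refill
jitter on that one date), so the realised uncovered run equals the drawn
duration; regular refills carry jitter, whose worst case (a few tens of
days) stays far below the 91-day gap, and truth is recorded from the
realised dates, never the intended plan.

### What the generator does *not* emulate

Passing recovery tests on synthetic cohorts shows the estimators are
consistent under the generator's assumptions, not that real registry data
satisfies them. In particular the generator has no mortality or migration
(patients persist to the window end, so yearly denominators grow toward the
window end rather than turning over), no dose switching within a patient,
no drug-specific prices, no seasonal dispensing patterns, and an
antiandrogen-only contamination that is independent of region and age. The
mean *annual* prevalence that emerges from `p_intermittent = 0.17` is
therefore an output of these assumptions, not a calibrated match to any
particular registry's annual figure.

## Numerical and design choices

* **Age rule** is evaluated at the first dispensation date; the enrolment
  moment is the natural reference and the choice is explicit and
  configurable through the filter's arguments.
* **Region-year exclusions are never automatic.** `qc_region_years()`
  flags any region-year below half its region's median annual count
  (regions observed ≥ 3 years only — a median of fewer years is not
  meaningful), but dropping a stratum is always an explicit configuration,
  because such drops are judgement calls that should be visible in the
  config echo, not buried in a heuristic.
* **Same-day duplicates** merge with units summed: registry extracts
  commonly split one pharmacy visit across rows.
* **Half-open coverage**: a dose dispensed on day $t$ covering $e$ days
  covers $[t, t+e)$; the day coverage ends is the first uncovered day.
  Degenerate inputs (a single dispensation, an empty stratum, a zero
  denominator) raise typed conditions (`adtgaps_error_*`,
  `adtgaps_warning_empty_stratum`) rather than returning silent zeros.
* **Costs** are attributed to the calendar year of the dispense date, as
  pharmacy expenditure accounting does, and the per-dispensation SD is the
  sample SD.
* **Problem sizes in the tests** — fuzzing 1,000 random histories against
  the day-grid oracle, recovery on 20 cohorts of 1,000 patients across
  four intermittency levels and five seeds, and one shared 5,000-patient
  cohort for distributional checks — were chosen as the smallest sizes at
  which the binomial 99% envelopes are informative.

## Known limitations

* Antiandrogen monotherapy during an LHRH gap does **not** disqualify the
  gap: off periods are defined purely by LHRH coverage. Whether such gaps
  are clinically intermittent is a sensitivity question the package leaves
  to the `min_gap_days` / formulary overrides.
* Clinical appropriateness (e.g. PSA-confirmed castration before a pause)
  is not computable from dispensations and is out of scope.
* Population-denominator prevalence (per male inhabitants) needs external
  census counts; the package computes only cohort-internal prevalences.
* The formulary encodes exactly the printed depot table it targets; local
  markets with other presentations should load an override TSV.

## A worked run

```{r example, eval = FALSE}
cfg <- simulate_config(n_patients = 1000, seed = 1)
cohort <- simulate_cohort(cfg)
res <- adt_run(cohort$records)
res
glance(res)
plots <- adt_report(res)
```
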