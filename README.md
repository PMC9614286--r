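# adtgaps

Reconstruction of androgen-deprivation treatment episodes from pharmacy
dispensation records, and estimation of how often prostate-cancer patients
are treated *intermittently*.

## The problem

Depot LHRH analogues (leuprorelin, triptorelin, goserelin, buserelin,
histrelin, nafarelin) suppress testosterone for a drug/dose-specific
nominal duration — 1, 2, 3, 6 or 12 months. Intermittent androgen
deprivation (IAD) deliberately pauses treatment between such depots;
continuous deprivation (CAD) does not. Dispensation registries record the
refill dates but not the intent, so intermittency must be inferred from
gaps in pharmacological coverage. `adtgaps` is for pharmacoepidemiologists
working with such claims/dispensation extracts.

For a patient with LHRH dispensations at dates `t_1 < … < t_n`, each
conferring `e_i` days of coverage (formulary duration × units), coverage
ends at the running maximum `c_i = max(c_{i-1}, t_i + e_i)` (early refills
stockpile). An interval with uncovered run `u_i = max(0, t_{i+1} - c_i)` of
at least `min_gap_days` (default 91 = three nominal months, a conservative
floor) that ends in a **confirmed re-initiation** is a potentially
intermittent interval time (PIIT). From the detected off periods the
package estimates:

- **P_IAD** — patients with ≥ 1 off-period day in a year / patients with
  ≥ 1 day of LHRH coverage that year, with Wilson 95% CIs; plus the global
  (ever-intermittent) share and the unweighted mean of the annual values;
- **%IAD** — total off-period days / total days between first and last
  dispensation;
- off-period duration summaries (median, IQR, range, in months), region ×
  year stratification, chi-square comparisons, and expenditure per
  drug/class/year/region normalised as euros per dispensation.

A seeded synthetic generator (`simulate_cohort()`) produces registry-shaped
cohorts with known ground truth (true regimen and off periods per patient)
for validating the whole pipeline.

## Worked example

```r
library(adtgaps)

cfg    <- simulate_config(n_patients = 1000, seed = 1)
cohort <- simulate_cohort(cfg)
res    <- adt_run(cohort$records)
res
#> ADT intermittency analysis
#>   patients: 884 (138 ever intermittent, 15.6%)
#>   mean annual P_IAD: 9.2%
#>   %IAD (time off treatment): 4.9%

res$prevalence[res$prevalence$region == "all", ]
#> # A tibble: 5 × 8
#>    year region n_treated n_intermittent  p_iad ci_low ci_high underestimated
#>   <int> <chr>      <int>          <int>  <dbl>  <dbl>   <dbl> <lgl>
#> 1  2012 all          346             38 0.110  0.0811  0.147  FALSE
#> 2  2013 all          505             69 0.137  0.109   0.169  FALSE
#> 3  2014 all          658             62 0.0942 0.0742  0.119  FALSE
#> 4  2015 all          814             65 0.0799 0.0631  0.101  FALSE
#> 5  2016 all          884             37 0.0419 0.0305  0.0572 FALSE
```

Of the 1,000 simulated patients, 884 survive the exclusion filters (under-18
and antiandrogen-only subjects are dropped; the exclusion log in
`res$exclusion_log` reconciles every patient). 138 are ever intermittent —
matching the generator's ground truth exactly — and the annual prevalence
falls towards the window end because pauses are sparse in time, the same
phenomenon that makes the global share (15.6%) overstate any single year.
`glance(res)` gives the one-row summary, `tidy(res)` the prevalence table,
and `adt_report(res)` the prevalence-trend, cost-by-drug and
age-distribution charts.

Real extracts enter through `read_records()` (canonical CSV schema:
`patient_id, birth_date, region, dispense_date, drug_name, atc_code,
dose_mg, n_units, cost_eur`), then the same `adt_run()`.

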