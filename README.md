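# ascertain

Quantifying under-ascertainment of Aboriginal and Torres Strait Islander
status in linked administrative health records.

Hospital separation records and death notifications each carry an
Indigenous-status flag, and for the same person the flag is inconsistently
recorded across occasions — usually in the false-negative direction. Any
count of Aboriginal patients based on a single record per person is
therefore an undercount. When a person's admission history and death record
are linked, their status can instead be determined from the whole history,
and the shortfall of the single-record count can be measured. `ascertain`
implements that analysis end to end for a cardiovascular-admission cohort,
for epidemiologists and health-data analysts working with linked extracts
(or, in their absence, with the bundled synthetic-cohort generator).

## What it computes

Given admissions and deaths extracts, the pipeline:

1. builds a **linked cohort**: per person, the most recent public-hospital
   CVD separation in the study window (the *index admission*, ages 25–74,
   ICD-10-AM I00–I99 by default), all admissions in the preceding 20 years
   excluding same-day routine-dialysis separations (V56 / Z49), and any
   subsequent death record;
2. determines each person's status under **four rules** using progressively
   more data — index only; index or death; majority (≥ 50%) of stated
   hospital flags or death; ever positive in any record or death;
3. derives the **under-ascertainment statistics**. For a baseline count
   *b* (index rule) and revised count *r*:

   - excess: (*r*/*b* − 1) × 100,
   - under-ascertainment: |*b*/*r* − 1| × 100,
   - Wilson score intervals for proportions (complement scale
     (1 − *p*) × 100 for shortfalls),
   - relative risks with Katz log-normal intervals
     exp(log RR ± z·√(1/a − 1/n₁ + 1/b − 1/n₂)),
   - a death-record cross-tabulation whose missing-versus-stated relative
     risk measures *informative missingness* — whether flags are absent
     preferentially for people identified as Aboriginal elsewhere;
4. stratifies under-ascertainment by sex, age band, SEIFA quintile, ARIA
   remoteness and region, with identifier-completeness audits and
   chi-square comparisons across strata.

A seeded generator (`simulate_cohort()`) produces synthetic extract pairs
with the assumed misclassification structure — stratum-dependent recording
sensitivity, within-person flag persistence, near-zero false positives,
informatively missing death flags (ratio 1.9 by default), era-split coding
— plus closed-form expectations (`expected_counts()`,
`expected_missingness_rr()`) and a parameter-recovery harness
(`recovery_experiment()`).

## Worked example

```r
library(ascertain)

params  <- simulation_params(n_persons = 20000, seed = 2026)
sim     <- simulate_cohort(params)
cohort  <- build_cohort(sim$admissions, sim$deaths)
cohort
#> <linked_cohort>
#>   20000 persons; 237763 history records (11.9 per person)
#>   6313 attached deaths; 0 anomalies

results <- classify_status(cohort)
tabulate_ascertainment(results)
#> # A tibble: 3 × 6
#>   method   morbidity_alone death_alone combined excess_pct underestimate_pct
#>   <chr>              <int>       <int>    <int>      <dbl>             <dbl>
#> 1 index               1023          54     1077        5.3               5
#> 2 majority            1116          28     1144       11.8              10.6
#> 3 ever                1339          10     1349       31.9              24.2
```

Reading the table: 1,023 persons are flagged Aboriginal on their index
admission alone; linking the death record adds 54; using the full 20-year
history under the ever rule brings the combined total to 1,349 — so the
unlinked index count understates the ever-identified count by 24.2%
(equivalently, linkage adds 31.9% more cases over the baseline).

```r
death_cross_tab(results)
#> <death_crosstab>
#> # A tibble: 5 × 7
#>   death_flag hmdc_positive hmdc_other total pct_hmdc_positive pct_low pct_high
#>   <chr>              <int>      <int> <int>             <dbl>   <dbl>    <dbl>
#> 1 positive             284         10   294              96.6    93.9     98.1
#> 2 negative             152       5646  5798               2.6     2.2      3.1
#> 3 stated               436       5656  6092               7.2     6.5      7.8
#> 4 missing               32        189   221              14.5    10.4     19.7
#> 5 total                468       5845  6313               7.4     6.8      8.1
#>   deaths flagged positive on death record: 294
#>   identified as Aboriginal in either source: 478
#>   death-record under-ascertainment: 38.5% (95% CI 34.2 to 42.9)
#>   missingness relative risk: 2.0 (95% CI 1.5 to 2.8)
```

Of 478 deceased persons identified as Aboriginal in either source, only
294 were flagged on the death record — a 38.5% shortfall in this synthetic
cohort. Deaths with a *missing* status flag were hospital-identified at
14.5% versus 7.2% for deaths with a stated flag (relative risk 2.0): the
missingness is informative, concentrated among people identified as
Aboriginal elsewhere.

```r
underestimation_by_factor(results, "aria")
#> # A tibble: 5 × 5
#>   factor level index_count ever_count underestimate_pct
#>   <chr>  <chr>       <int>      <int>             <dbl>
#> 1 aria   1             181        325                80
#> 2 aria   2              79        148                87
#> 3 aria   3             157        233                48
#> 4 aria   4             209        223                 7
#> 5 aria   5             397        420                 6
```

The configured sensitivity gradient surfaces directly: under-ascertainment
is far worse in metropolitan and urban strata (ARIA 1–2) than in remote
and very remote ones (ARIA 4–5).

Published contingency-table counts can be fed to the same machinery
directly, e.g. `ascertainment_table(c(3060, 3094, 3636), c(83, 78, 60))`
or `death_cross_tab_counts(positive = c(654, 60), negative = c(188, 18048),
missing = c(73, 786))`, and `wilson_interval(714, 975, complement = TRUE)`
gives 26.8% (24.1, 29.6).

A command-line wrapper ships at `inst/cli/ascertain.R` with `simulate`,
`analyse` and `recover` subcommands over the same functions.

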