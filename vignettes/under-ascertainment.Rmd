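---
title: "Quantifying under-ascertainment of Indigenous status in linked hospital and death records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying under-ascertainment of Indigenous status in linked hospital and death records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ascertain)
library(dplyr)
```

## The problem

Administrative health collections under-record Aboriginal and Torres Strait
Islander status. The flag is recorded at each hospital admission and on
each death notification, and for the same person it is often positive on
some records and negative or absent on others: whether the question is
asked, who answers it, and what the shared patient-management system
carries forward all vary by occasion. A count of Aboriginal patients based
on one record per person is therefore an undercount, and the size of the
shortfall matters wherever hospitalisation or mortality rates for
Aboriginal people are reported.

Record linkage offers a correction: if a person's admissions over many
years and their death record are linked, their status can be determined
from the whole history rather than a single record. `ascertain` implements
that analysis as a reusable pipeline for a cardiovascular-admission cohort:
cohort construction from linked extracts, four person-level
status-determination rules, the associated under-ascertainment and bias
statistics, stratified summaries, and a synthetic-cohort generator so that
every stage is testable without access to confidential linked data.

## Cohort construction

The cohort definition ([`cohort_spec()`]) selects, for each person, the
most recent public-hospital separation in a study window (default
2000--2005) with a principal diagnosis in ICD-10-AM chapter I (circulatory
disease) at ages 25--74 — the *index admission*. Ties on separation date
break by latest admission date, then stable input order. Around the index,
the *lookback history* collects all admissions, any cause, public and
private, whose admission date lies in the half-open window
`(index - 20 years, index]`. Same-day separations for routine dialysis
(ICD-9-CM V56, ICD-10-AM Z49) are excluded: chronic dialysis patients
otherwise contribute hundreds of clinically uninformative records.
An overnight dialysis admission is retained — the exclusion requires the
same-day condition. A death record attaches when it falls on or after the
index separation and inside the window; persons who died in-window without
an in-window admission are never cohort members.

Two choices here were genuinely open and are configurable rather than
imposed. Age eligibility is evaluated from the age recorded on the
qualifying admission (admission-time age is what morbidity collections
carry). The 20-year lookback is measured from the index *admission* date;
measuring from the separation date would shift the window by a few days of
length of stay and is immaterial for any realistic history.

## Interpreting the status flag

Raw codes differ by era: the legacy binary coding (1 = not Aboriginal,
2 = Aboriginal) and the four-category coding (1 = Aboriginal, 2 = Torres
Strait Islander, 3 = both, 4 = neither, with provision for "not stated").
`interpret_status()` reduces both to a tri-state flag
(positive / negative / missing), with two consequential rules:

* codes 1--3 all count as positive by default — the analysis targets a
  single combined Indigenous-status flag, and Torres Strait Islander-only
  responses are counted in it by convention (`tsi_as_positive = FALSE`
  reverses this);
* in WA public hospitals "not stated" is keyed identically to "neither",
  so an absent four-category code from that source reads as *negative*,
  not missing. Death records and other hospitals retain a genuine missing
  state.

The historical bulk recode of legacy values (1 to 4, 2 to 3) is exposed as
`recode_legacy_status()`, and interpreting a legacy code directly always
agrees with interpreting its recoded four-category value — a property the
test suite checks for every source.

## The four determination rules

For each person, `classify_status()` evaluates:

1. **index** — positive flag on the index admission (baseline, most
   conservative);
2. **index + death** — index or subsequent death record positive;
3. **majority + death** — at least 50% of *stated* hospital flags (index
   plus lookback) positive, or death record positive;
4. **ever + death** — any hospital record or death record positive (least
   conservative).

Missing flags are excluded from the majority rule's numerator and
denominator; a person with no stated hospital flag is classified by the
death record alone. An exact 50% share counts as positive ("at least
50%"). The death record is an OR-term in rules 2--4, never part of the
majority denominator. The majority denominator includes the index record.

Rules 2--4 each contain rule 1, and rule 4 contains all others, so those
count orderings hold on every input. The index and majority rules are
*not* mutually nested — a person whose index flag is positive but whose
history is mostly negative satisfies (ii) and not (iii) — so the familiar
ladder `index <= index+death <= majority+death <= ever+death` is an
empirical regularity of data recorded with reasonably high sensitivity,
not a logical law. The tests assert the guaranteed orderings on arbitrary
cohorts and the full ladder under study-like conditions.

`tabulate_ascertainment()` (or `ascertainment_table()` from published
counts) splits each rule's total into morbidity-records-alone versus added
by death records and derives two percentages against the index baseline
$b$ and a revised count $r$:

* excess: $(r/b - 1) \times 100$;
* under-ascertainment: $|b/r - 1| \times 100$.

Both are reported, as the two views are easily conflated: an excess of
20.8% corresponds to an under-ascertainment of 17.2%.

## Statistical estimators

**Wilson score interval.** Proportions carry Wilson score intervals, with
a complement scale $(1-p)\times 100$ for reporting under-ascertainment.
The Wilson interval is used deliberately: on the benchmark death-record
computation (714 of 975) it yields (24.1, 29.6) on the complement
percentage scale, where a Wald interval gives (24.0, 29.5); only the
score interval reproduces the reference values. An independent route
(`prop.test(correct = FALSE)`) cross-checks the implementation in the
tests.

**Relative risk.** `relative_risk()` uses the Katz log-normal interval,
$\exp(\log RR \pm z\sqrt{1/a - 1/n_1 + 1/b - 1/n_2})$. Zero numerators
flag the interval undefined rather than silently continuing.

**Chi-square.** Pearson's test without continuity correction via
`stats::chisq.test()`, with a warning when any expected count falls below
5.

**Death cross-tabulation.** `death_cross_tab()` tabulates the death-record
flag (positive / negative / missing) against hospital-derived status. The
hospital-derived column uses the ever rule *restricted to hospital
records*: letting the death record into its own comparator would be
circular. Derived quantities: the total identified in either source, the
death-record shortfall with Wilson complement interval, per-row
hospital-positive percentages, and the informative-missingness relative
risk — hospital-identified probability among deaths with a missing flag
versus a stated flag. A ratio above 1 means missingness is informative:
the flag is more likely to be absent precisely for people identified as
Aboriginal elsewhere, so missing-at-random corrections would understate
the bias.

**Rounding.** Report output rounds half-up to one decimal (whole percent
for stratified summaries), matching reporting convention; all internal
computation is full precision. `round_half_up()` is exported because R's
`round()` uses banker's rounding, which disagrees on exact halves.

Numbers this package reproduces exactly from published inputs, and which
the acceptance script recomputes: the ladder 2.7/3.7/20.8 (excess) and
2.6/3.5/17.2 (shortfall); death-record under-ascertainment 26.8%
(24.1--29.6); missingness relative risk 1.9 (1.5--2.4) with row
percentages 8.5% vs 4.4%; stratified shortfalls such as male 18% and very
remote 6%.

## Stratified summaries

`underestimation_by_factor()` compares index-identified against
ever-identified counts per level of sex, age group, SEIFA quintile, ARIA
category or region, taking each person's attributes from the index
admission (the natural anchor when attributes differ across records).
Persons with absent SEIFA or ARIA form an explicit `"unknown"` level —
silently dropping them would bias strata that under-collect geography.
Two age-band presets exist because completeness audits (00-24 / 25-44 /
45-64 / >65) and stratified summaries (0-34 / 35-64 / 65+) conventionally
use different bands; both are available via `age_band()`.
`completeness_by_stratum()` audits identifier missingness by region, age
band, sex, and recording period, and `compare_strata()` feeds an r-by-2
newly-identified versus index-identified table to the chi-square test.

## The synthetic-cohort generator

Confidential linked extracts cannot be distributed, so
`simulate_cohort()` generates them with the misclassification structure
the analysis assumes. Its defaults are fixed study conditions, chosen once
to emulate the state-wide cardiovascular cohort; they are not tuned to
reproduce any published count:

* `n_persons = 62692`, one qualifying index CVD admission each, and a
  Poisson(11) number of lookback admissions truncated at $\ge 1$, giving
  roughly twelve records per person over the 20-year history;
* latent prevalence `prop_true_positive = 0.06`, slightly above the
  ever-identified rate a cohort of this kind observes, since recording
  sensitivity is below 1;
* per-record flag sensitivity varying by ARIA, age band and SEIFA
  (`default_sensitivity_map()`): additive logit effects around a 0.85
  base, highest in remote/very-remote and disadvantaged strata, lowest
  for older metropolitan patients — the qualitative gradient reported in
  audits of these collections. Truly positive persons are also drawn with
  more remote, more disadvantaged, younger profiles;
* `false_positive_rate = 0.001` (misclassification is overwhelmingly
  false-negative);
* `within_person_correlation = 0.4`: each record copies the previous
  recorded flag with this probability, else is re-drawn — the shared
  patient-management system perpetuating earlier classifications. The
  marginal per-record sensitivity is unchanged by the copying, but the
  ever rule gains less from each additional record than independence
  would predict;
* deaths with probability 0.35 (positive) / 0.31 (negative), reflecting
  both the cohort's ~2.5-year average follow-up after a late-window index
  and higher Aboriginal CVD mortality; a stated death flag is positive
  with probability 0.73 for truly positive persons;
* death-flag missingness 0.076 (positive) versus 0.04 (negative) — ratio
  1.9, the informative-missingness target — around an overall missing
  share of ~4% of deaths;
* hospital-flag missingness defaults to 0 (real histories show only a
  handful of missing hospital flags) and, when configured, applies to
  private-sector records only: a missing flag at a WA public hospital is
  not representable, because the collapsing rule reads absence as
  negative. Records before 2000 are emitted in the legacy binary coding
  (missing ones necessarily as absent four-category codes), later ones in
  the four-category coding, exercising the recode path;
* a 1% sprinkling of same-day dialysis records exercises the cohort
  builder's exclusion.

The generator is vectorised and fully deterministic given `seed`; two
runs produce byte-identical CSVs.

### Closed-form expectations and recovery

For the copy-chain, the probability that a truly positive person with $k$
records is ever flagged positive has the closed form

$$P(\text{ever}) = 1 - (1-s)\,\bigl(\rho + (1-\rho)(1-s)\bigr)^{k-1},$$

reducing to $1-(1-s)^k$ at $\rho = 0$ (`expected_ever_sensitivity()`,
validated against exhaustive enumeration of chain outcomes).
`expected_counts()` integrates this over the stratum distribution and the
truncated-Poisson record count to give expected identification rates, and
`expected_missingness_rr()` gives the expected cross-tab relative risk
from the configured death and missingness probabilities. The expected RR
sits slightly below the configured missingness ratio (about 1.77 versus
1.9 under the defaults) because the stated-row denominator is not fully
status-balanced at non-zero prevalence; `recovery_experiment()` therefore
reports both the configured ratio and the closed-form expectation next to
the pipeline estimate, with Monte-Carlo standard errors (the estimator's
own sampling SE for a single replicate, the SE of the replicate mean
otherwise). These expectations ignore the two second-order effects of
excluded dialysis records and configured hospital-flag missingness; the
recovery tests run with those at or near zero.

### What the simulator does and does not emulate

The generator reproduces the *mechanisms* — stratum-dependent
sensitivity, within-person persistence, near-zero false positives,
informatively missing death flags, era-split coding — not Western
Australia's population structure or any published count. Passing
recovery tests show the pipeline correctly measures what the generative
model produces; they cannot show that the generative model is the true
data-generating process of any real collection. Real extracts add
features the simulator omits: migration in and out of state, attribute
changes across records (the simulator holds sex, region and SEIFA fixed
per person), duplicate or near-duplicate records surviving linkage error,
and secular trends in recording practice within eras.

## Problem sizes and numerical choices

The test suite exercises the pipeline at 100--15,000 synthetic persons and
the recovery acceptance check at 50,000 (one replicate, judged against
three Monte-Carlo SEs); the full default of 62,692 persons with ~750,000
records simulates in well under a minute. Validation is report-collecting
by default — administrative extracts are dirty, and dropping a bad row
with a recorded reason beats aborting a 20-year extract — with a strict
mode for pipelines that prefer failure. Duplicate death records abort in
either mode, since at-most-one-death-per-person is structural, not
row-level. Dates are ISO-8601 calendar dates; diagnosis matching strips
dots and upper-cases before prefix comparison, so `"I"` covers I00--I99
and `"Z49"` covers Z49.x.

## Known limitations

* Status determination is deterministic; no probabilistic or Bayesian
  estimation of latent status, and no capture-recapture modelling of the
  sources.
* Linkage itself is taken as given: `person_id` must already be resolved.
* Published stratified confidence intervals are not reproduced (their
  method is not identifiable from point estimates); stratified output
  carries point estimates only.
* No multiple-testing correction is applied across strata comparisons.
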