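---
title: "Validating claims-based phenotyping algorithms with chart-review PPV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating claims-based phenotyping algorithms with chart-review PPV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoppv)
```

## The problem

Administrative claims are an attractive substrate for building disease
cohorts: every billed encounter carries diagnosis and procedure codes, and
no chart abstraction is needed. But codes are entered for billing, not for
research, and a single miscoded encounter can pull a patient without the
condition into a "case" cohort. Before a code-based definition — a
*computable phenotype* — is used to select patients, its positive
predictive value (PPV) should be measured against a gold standard,
typically medical-record review.

`phenoppv` implements that study design end to end for frequency-and-timing
rules over diagnosis code days, in the concrete setting of HIV diagnosis
codes among women enrolled in a U.S. health plan during 2010–2020, a window
that spans the 2015-10-01 switch from ICD-9-CM to ICD-10-CM coding. The
same machinery applies to any condition: code sets and algorithm
definitions are data (YAML configs), not code.

## The validation design

1. **Universe.** All cohort members with at least one HIV diagnosis code
   day during their follow-up. Follow-up accrues from cohort entry until
   the earliest of: a more-than-90-day gap in enrollment or primary-care
   attribution, a more-than-90-day gap in catchment-area residency, the
   90th birthday, death, or the administrative end of the study. No
   re-entry after exit.
2. **Gold standard.** Charts are reviewed in a ±6-month window around each
   code day, in chronological order, stopping at the first confirmation: a
   clinician's note stating the diagnosis, or in its absence laboratory
   evidence (any detectable viral load, or positive antibody testing). The
   patient's confirmation date is the *earliest validated code day*, not
   the date of the note or laboratory result.
3. **Algorithms.** Each rule is "at least *k* distinct days with a code
   from set *S*", optionally restricted to a calendar window, optionally
   with a companion clause (at least one CD4 procedure day on or after the
   first HIV code day). The unit is the distinct calendar day: three claim
   lines on one day count once.
4. **Statistic.** For each algorithm, `N` = patients meeting the criteria
   during follow-up; `n` = those whose confirmation date falls on or
   before the date the criteria were met; PPV = `100·n/N` with a Wilson
   95% confidence interval.

This design estimates PPV only. Because the universe is conditioned on
having at least one code, sensitivity, specificity and NPV are not
estimable and are deliberately out of scope.

## Key decisions and their rationale

Several details are under-determined by the design above; the package
resolves them as follows.

* **"±6 months" is ±183 days.** Calendar-month arithmetic is ambiguous at
  month ends; a fixed day count is reproducible. The half-width is a
  parameter (`window_days`).
* **Closed intervals everywhere.** Calendar windows, follow-up `[entry,
  exit]`, and review windows include both endpoints; "on or before" a
  cutoff includes the cutoff day.
* **Gap censoring lands on the last covered day** before the gap, so
  follow-up contains only covered time. A gap of exactly the threshold (90
  days) does *not* censor — "more than 90 days" is read strictly. Gaps of
  up to 90 days are bridged, and the uncovered days inside them still
  accrue follow-up. A coverage record that simply stops before the study
  end censors at its last day if more than 90 uncovered days remain to the
  study end; otherwise the gap is not observable as "more than 90 days"
  and the patient is administratively censored at the study end.
* **The day a patient turns 90** is no longer eligible; censoring falls on
  the 90th birthday minus one day. The design source does not pin this
  down; one day either way is immaterial at cohort scale.
* **Tie-breaking.** When several censoring events fall on one date, the
  exit reason is attributed in the fixed order disenrollment/PCP gap,
  residency gap, age, death, administrative end. Insurance intervals are
  keyed by start date; if two intervals start on the index date, the
  later-listed start wins — a deterministic tie-break.
* **Era windows gate eligibility on the first code day falling *inside*
  the window**, not merely on or after its start. This is what makes the
  sub-era universes additive partitions (early-era plus late-era equals
  era, era plus era equals overall); the on-or-after reading would count
  late-indexing patients in every earlier sub-window and break additivity.
* **Individual-code rows** gate eligibility on the first *any*-HIV code
  day (era membership) while counting days with the *specific* code. A
  patient indexing in the ICD-9 era therefore contributes to each
  individual ICD-9 code they ever carry, which is why individual-code
  denominators sum to more than the era denominator.
* **Companion clauses** are not met until both parts hold: the criteria-met
  date is the later of the *k*-th primary code day and the earliest
  companion day on or after the first primary code day. Companion days
  before the first code day are ignored.
* **The O98.711–O98.73 range** is an explicit enumeration of the six valid
  ICD-10-CM codes (O98.711, O98.712, O98.713, O98.719, O98.72, O98.73);
  unlisted O98.7x subcodes are rejected rather than silently matched.
* **Codes are stored dot-free and uppercase**, as strings (ICD-9 leading
  zeros are significant). Readers accept dotted or undotted input;
  normalization is idempotent.
* **Rounding is half-up to one decimal** on the percent scale, the
  convention of published clinical tables; base R's round-half-to-even
  would turn 93.95 into 93.9.
* **The Wilson `z` is the exact normal quantile** (1.959964...), not 1.96;
  at one-decimal rounding both choices agree on every cell of the
  reference table.
* **Zero-denominator cells** are flagged not-estimable and rendered `N/A`
  instead of being dropped, keeping table shape stable.

## What the synthetic-data generator emulates

Real chart-review data cannot be shipped, so the package generates
synthetic inputs with known per-patient truth. The generator reproduces
the *structure* the pipeline consumes — not any real patient population:

* a code-positive universe (every patient has at least one HIV code day in
  follow-up), with the index day drawn from either coding era
  (probability 0.51 for the ICD-9 era, matching the observed 139/272
  split);
* latent truth per patient: `truly_hiv` (probability 0.835 given coded)
  and a true diagnosis date. With probability 0.04 the first code day
  *precedes* the true diagnosis (a premature code the chart cannot
  confirm) — this single mechanism generates the study's signature
  phenomenon, a first-code PPV (~80%) well below the second-code PPV
  (~94%);
* recurring code days for true cases (`1 + Poisson(4)` days, mean gap 120
  days) versus mostly isolated days for false positives
  (`1 + Binomial(2, 0.15)`);
* era-appropriate vocabulary per code day, with per-era mixture weights
  calibrated so the rare codes (079.53, 795.71, B97.35, the O98 group)
  stay rare, as in the reference table;
* CD4 procedure days after index with probability 0.92 (true) / 0.12
  (false), plus occasional pre-index CD4 days that companion clauses must
  ignore;
* chart records in chronological order up to the first confirmation;
  confirmations carry clinician-note evidence with probability 0.987,
  otherwise laboratory evidence — the observed evidence mix;
* follow-up after index drawn log-normal (median 2.0 years), exit reasons
  mixed to roughly the observed distribution, realized in the coverage
  spans so that the cohort builder recovers them;
* cosmetic demographics (age log-normal with median 40 and IQR ≈ 32–49,
  race/ethnicity and payer from the observed marginals) that no
  computation uses.

Determinism: the generator is a pure function of the seed, and per-patient
random streams are split by patient index, so enlarging the cohort
reproduces existing patients exactly.

What passing tests on synthetic data do **not** show: the generator draws
code days independently given truth, has no seasonality, no coding-practice
drift within an era, no inpatient/outpatient structure (the setting field
is carried but unused, as in the evaluated rules), and chart abstraction is
error-free by construction. Results on real claims depend on local coding
practice and chart completeness, which only a real chart-review study can
measure.

## Numerical and testing notes

* **Wilson coverage is checked honestly.** The exact coverage of a score
  interval oscillates with binomial discreteness: at `N = 10` it ranges
  from about 93.0% (`p = 0.1`) to 98.1% (`p = 0.94`). The test suite
  therefore checks each `(p, N)` cell's empirical coverage against the
  exact analytic coverage (within Monte-Carlo tolerance) and asserts the
  near-nominal band 93.5–96.5% on coverage pooled over the grid of
  `p ∈ {0.1, 0.5, 0.8, 0.94}`, `N ∈ {10, 50, 272}` at 20,000 replicates
  per cell, where the oscillation averages out (pooled exact coverage
  95.7%).
* **Two independent oracles** guard the core logic: the rule engine is
  compared with a brute-force scan over all candidate dates, and the
  stop-at-first-confirmation adjudicator with an exhaustive scan over all
  (code day, record) pairs, on hundreds of random synthetic patients.
  The Wilson closed form is checked against score-test inversion by root
  finding.
* **Reference-table reproduction.** Feeding the published per-algorithm
  `(N, n)` counts through `evaluate_counts()` reproduces every printed
  Wilson bound and 15 of the 17 estimable PPVs exactly at one-decimal
  rounding. The two exceptions (213/219 printed 97.2, 25/33 printed 75.7)
  are printing inconsistencies in the source table itself: no rounding
  convention produces all its printed digits (108/139 printed as 77.7
  requires rounding; those two cells require truncation). The package
  rounds half-up and computes 97.3 and 75.8.
* **Problem sizes.** Tests run the full pipeline on cohorts of 50–272
  patients and aggregate 50 replicate 272-patient cohorts for the
  parameter-recovery check; the coverage simulation uses 20,000 replicates
  per cell. These sizes give Monte-Carlo error comfortably below the
  tolerances asserted.

## A worked example

```{r example, eval = FALSE}
library(phenoppv)

# 1. simulate a calibrated 272-woman cohort and run the whole pipeline
res <- run_pipeline(sim_config = calibration_preset(seed = 1), quiet = TRUE)
res$validation_table[res$validation_table$algorithm_id %in%
                       c("1a", "1b", "1c"),
                     c("algorithm_id", "N", "n", "ppv_pct",
                       "ci_low_pct", "ci_high_pct")]

# 2. printed-counts mode: the statistics without any patient-level data
counts <- read.csv(system.file("extdata", "published_validation_counts.csv",
                               package = "phenoppv"))
evaluate_counts(counts[counts$algorithm_id == "1b", ])

# 3. define a custom algorithm: two Z21 days in the ICD-10 era
spec <- algorithm_spec("z21x2", "two asymptomatic-status days",
                       "icd10_Z21", min_distinct_days = 2,
                       window = as.Date(c("2015-10-01", "2020-12-31")),
                       restrict_first_code_to_window = TRUE)
```

## Limitations

PPV is the only accuracy measure this design can estimate. The calibration
preset matches marginal structure, not patient-level joint distributions —
the generator's code-recurrence intensity given truth is a modelling
choice, constrained only by the marginal table it was calibrated to. The
era calendar models a single institution-wide switch date; mixed-vocabulary
transition periods would need a claim-level era assignment instead.
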