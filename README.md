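# phenoppv

Validation of claims-based computable phenotypes by chart-review positive
predictive value (PPV), with Wilson score confidence intervals.

## The problem

Researchers often define disease cohorts from administrative claims alone:
"a patient has condition X if their claims show at least *k* days with a
diagnosis code for X". Such rules are cheap to run but only as good as the
coding, so they are validated against a medical-record gold standard by
estimating the PPV — among patients the rule selects, the share whose chart
confirms the diagnosis on or before the day the rule's criteria were met.

`phenoppv` implements that study design end to end for HIV diagnosis codes
among women health-plan enrollees during 2010–2020, spanning the 2015-10-01
ICD-9-CM → ICD-10-CM transition:

* **code sets & eras** — normalized diagnosis/procedure vocabularies
  (ICD-9: 042, V08, 079.53, 795.71; ICD-10: B20, Z21, B97.35,
  O98.711–O98.73; CPT 86360/86361 for CD4 testing) and an era calendar
  (`hiv_codesets()`, `era_calendar()`);
* **cohort** — follow-up accrual under >90-day enrollment/residency gap,
  age-90, death and administrative censoring; index = first HIV code day
  in follow-up (`build_followup()`, `find_index_events()`);
* **gold standard** — chronological chart review within ±183 days of each
  code day, stopping at the first confirmation; the confirmation date is
  the earliest validated code day (`adjudicate()`);
* **algorithms** — a declarative engine for "≥ k distinct code days"
  rules with calendar windows and companion procedure clauses
  (`algorithm_spec()`, `builtin_algorithm_specs()`);
* **statistics** — PPV with Wilson 95% intervals and validation-table
  assembly (`wilson_interval()`, `validation_table()`,
  `evaluate_counts()`);
* **synthetic data** — a calibrated generator with known per-patient truth
  so the whole pipeline runs with no real data (`simulate_cohort()`,
  `calibration_preset()`).

For a denominator of `N` rule-positive patients with `n` chart-confirmed,

```
PPV = 100 · n / N,   Wilson CI: (p̂ + z²/2N ± z·√(p̂(1−p̂)/N + z²/4N²)) / (1 + z²/N)
```

with `z = Φ⁻¹(0.975) ≈ 1.959964`.

## Worked example

```r
library(phenoppv)

res <- run_pipeline(sim_config = calibration_preset(seed = 42), quiet = TRUE)
head(res$validation_table[, c("algorithm_id", "N", "n",
                              "ppv_pct", "ci_low_pct", "ci_high_pct")], 3)
#>   algorithm_id   N   n ppv_pct ci_low_pct ci_high_pct
#> 1           1a 272 224    82.4       77.4        86.4
#> 2           1b 228 221    96.9       93.8        98.5
#> 3           1c 193 191    99.0       96.3        99.7
```

Row `1a` says: of the 272 simulated women with ≥1 HIV diagnosis code day,
224 had a chart-confirmed diagnosis as of that first code day — PPV 82.4%
(Wilson 95% CI 77.4–86.4%). Requiring a second code day (`1b`) shrinks the
denominator to 228 but raises the PPV to 96.9%: isolated miscodes rarely
recur. The generator's configured truth makes ~80% of coded women
confirmable at the first code day, which the pipeline recovers.

The statistics also run directly from published per-algorithm counts,
without patient-level data:

```r
counts <- read.csv(system.file("extdata", "published_validation_counts.csv",
                               package = "phenoppv"))
evaluate_counts(counts[counts$algorithm_id == "1a", ])[
  , c("N", "n", "ppv_pct", "ci_low_pct", "ci_high_pct")]
#>     N   n ppv_pct ci_low_pct ci_high_pct
#> 1 272 219    80.5       75.4        84.8
```

A thin CLI wrapper lives at `inst/cli/phenoppv.R`
(`simulate`, `run-all`, `evaluate-counts` subcommands).

See the vignette (`vignettes/validating-claims-phenotypes.Rmd`) for the
model, the censoring and adjudication rules, what the synthetic generator
does and does not emulate, and the numerical choices.

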