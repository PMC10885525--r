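test_that("simulation is deterministic and extension-stable by patient", {
  cfg <- simulation_config(n_patients = 40L, seed = 123L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  # byte-identical files
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(a, d1)
  write_simulation(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # adding patients never perturbs existing ones
  bigger <- simulate_cohort(simulation_config(n_patients = 60L, seed = 123L))
  expect_equal(bigger$claims[bigger$claims$patient_id %in%
                                   a$claims$patient_id, ],
                   a$claims, ignore_attr = TRUE)
  expect_equal(bigger$ground_truth[1:40, ], a$ground_truth,
                   ignore_attr = TRUE)
})

test_that("generated data respect the structural invariants", {
  sim <- simulate_cohort(simulation_config(n_patients = 150L, seed = 7L))
  enr <- merge_spans(sim$enrollment)
  fu <- build_followup(enr, sim$demographics, merge_spans(sim$residency))
  # claims fall inside enrollment coverage
  by_pat <- split(sim$claims, sim$claims$patient_id)
  for (pid in names(by_pat)) {
    spans <- enr[enr$patient_id == pid, ]
    covered <- vapply(by_pat[[pid]]$service_date, function(d) {
      any(spans$start <= d & d <= spans$end)
    }, TRUE)
    expect_true(all(covered))
  }
  # every patient indexes (the universe is code-positive women)
  idx <- find_index_events(sim$claims, fu, hiv_codesets()$all_hiv,
                           sim$demographics)
  expect_identical(nrow(idx), 150L)
  expect_true(all(idx$age_at_index >= 18 & idx$age_at_index <= 89))
  # chart targets are HIV code days
  days <- distinct_code_days(sim$claims, hiv_codesets()$all_hiv)
  for (i in seq_len(nrow(sim$chart_reviews))) {
    expect_true(sim$chart_reviews$target_code_date[i] %in%
                  days[[sim$chart_reviews$patient_id[i]]])
  }
  # a true case's diagnosis date exists; codes confirm only on/after it
  gt <- sim$ground_truth
  expect_true(all(!gt$truly_hiv | !is.na(gt$true_diagnosis_date)))
  conf <- sim$chart_reviews[sim$chart_reviews$confirmed, ]
  m <- match(conf$patient_id, gt$patient_id)
  expect_true(all(gt$truly_hiv[m]))
  expect_true(all(conf$target_code_date >= gt$true_diagnosis_date[m]))
})

test_that("forced prevalence limits drive the PPV to its extremes", {
  res1 <- run_pipeline(
    sim_config = simulation_config(n_patients = 60L, seed = 3L,
                                   prevalence_true_given_coded = 1,
                                   p_truth_after_first_code = 0),
    quiet = TRUE
  )
  est <- res1$validation_table[res1$validation_table$estimable, ]
  expect_true(all(est$ppv_pct == 100))

  res0 <- run_pipeline(
    sim_config = simulation_config(n_patients = 60L, seed = 3L,
                                   prevalence_true_given_coded = 0),
    quiet = TRUE
  )
  expect_true(all(res0$validation_table$n == 0))
})

test_that("pipeline counts equal counts derived directly from ground truth", {
  # parameter-recovery oracle: the pipeline must add no bias beyond the
  # adjudication rules, so n/N recomputed from latent truth + code days
  # matches the pipeline for every algorithm
  cfg <- simulation_config(n_patients = 120L, seed = 21L)
  res <- run_pipeline(sim_config = cfg, quiet = TRUE)
  sim <- res$sim
  gt <- sim$ground_truth
  fu <- res$followups
  days <- distinct_code_days(sim$claims, hiv_codesets()$all_hiv)
  # ground-truth confirmation date: first in-follow-up code day on/after the
  # true diagnosis date (NA when never confirmable)
  truth_conf <- vapply(seq_len(nrow(gt)), function(i) {
    if (!gt$truly_hiv[i]) return(NA_real_)
    f <- fu[match(gt$patient_id[i], fu$patient_id), ]
    d <- days[[gt$patient_id[i]]]
    d <- d[d >= f$entry & d <= f$exit & d >= gt$true_diagnosis_date[i]]
    if (length(d) == 0) NA_real_ else as.numeric(d[1])
  }, 0)
  truth_conf <- as.Date(truth_conf, origin = "1970-01-01")
  # adjudicated confirmations equal the ground-truth reconstruction
  m <- match(gt$patient_id, res$confirmations$patient_id)
  expect_identical(res$confirmations$confirmed[m], !is.na(truth_conf))
  expect_identical(res$confirmations$confirmation_date[m], truth_conf)
  # and so do the per-algorithm counts
  out <- res$outcomes
  for (id in unique(out$algorithm_id)) {
    o <- out[out$algorithm_id == id & out$in_denominator, ]
    k <- match(o$patient_id, gt$patient_id)
    n_truth <- sum(!is.na(truth_conf[k]) &
                     truth_conf[k] <= o$criteria_met_date)
    cell <- res$validation_table[res$validation_table$algorithm_id == id, ]
    expect_identical(cell$N, nrow(o))
    expect_identical(cell$n, n_truth)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(prevalence_true_given_coded = 1.2),
               "outside \\[0,1\\]")
  expect_error(simulation_config(code_weights_icd9 = c("042" = 0.5)),
               "sum to 1")
  expect_error(simulation_config(n_patients = 0), ">= 1")
  expect_error(simulation_config(mean_code_days_true = 0.5), "exceed 1")
})

test_that("the calibration preset encodes the study conditions", {
  cfg <- calibration_preset()
  expect_identical(cfg$n_patients, 272L)
  expect_equal(cfg$p_note_evidence, 0.987)
  expect_equal(configured_first_code_ppv(cfg),
               100 * 0.835 * 0.96)
})
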