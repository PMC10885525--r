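test_that("the k-th distinct code day sets the criteria-met date", {
  spec2 <- algorithm_spec("k2", "two days", "all_hiv", 2L)
  d <- as.Date(c("2016-01-01", "2016-02-01", "2016-03-01"))
  res <- evaluate_algorithm(spec2, d)
  expect_true(res$met)
  expect_identical(res$criteria_met_date, as.Date("2016-02-01"))

  expect_false(evaluate_algorithm(spec2, d[1])$met)
  expect_false(evaluate_algorithm(spec2, as.Date(character(0)))$met)
})

test_that("companion clauses require a procedure day on or after the first code day", {
  spec <- algorithm_spec("cd4", "HIV + CD4", "all_hiv", 1L,
                         companion_code_set_id = "cd4_cpt")
  hiv <- as.Date("2016-01-01")
  cd4 <- as.Date(c("2015-12-01", "2016-01-20"))
  res <- evaluate_algorithm(spec, hiv, cd4)
  expect_true(res$met)
  expect_identical(res$criteria_met_date, as.Date("2016-01-20")) # pre-index CD4 ignored

  # same-day companion qualifies; criteria-met is the later of the two parts
  same <- evaluate_algorithm(spec, hiv, as.Date("2016-01-01"))
  expect_identical(same$criteria_met_date, as.Date("2016-01-01"))
  expect_false(evaluate_algorithm(spec, hiv, as.Date("2015-12-01"))$met)
  expect_false(evaluate_algorithm(spec, hiv, as.Date(character(0)))$met)
})

test_that("window eligibility is inside-the-window, making sub-eras additive", {
  specs <- builtin_algorithm_specs()
  expect_true(eligible(specs[["3a"]], as.Date("2016-02-01")))
  expect_false(eligible(specs[["3a"]], as.Date("2014-01-01")))
  expect_true(eligible(specs[["1a"]], as.Date("2014-01-01"))) # no restriction
  # first code in the later sub-era is ineligible for the earlier one
  expect_false(eligible(specs[["3b"]], as.Date("2018-06-01")))
  expect_true(eligible(specs[["3c"]], as.Date("2018-06-01")))
})

test_that("the built-in suite matches the published rule definitions", {
  specs <- builtin_algorithm_specs()
  expect_identical(names(specs),
                   c("1a", "1b", "1c", "2a", "2b", "2c", "3a", "3b", "3c",
                     "4a", "4b", "4c", "4d", "5a", "5b", "5c", "5d", "6a"))
  expect_identical(specs[["1b"]]$min_distinct_days, 2L)
  expect_null(specs[["1b"]]$window)
  expect_identical(specs[["5d"]]$code_set_id, "icd10_pregnancy")
  expect_identical(specs[["5d"]]$min_distinct_days, 1L)
  expect_identical(specs[["6a"]]$companion_code_set_id, "cd4_cpt")
  expect_identical(specs[["2a"]]$window,
                   as.Date(c("2010-01-01", "2015-09-30")))
  expect_identical(specs[["3a"]]$window,
                   as.Date(c("2015-10-01", "2020-12-31")))
  # individual-code rows gate eligibility on any HIV code, count the specific code
  expect_identical(specs[["4a"]]$eligibility_code_set_id, "all_hiv")
  expect_identical(specs[["4a"]]$code_set_id, "icd9_042")
  expect_true(specs[["4a"]]$restrict_first_code_to_window)
})

test_that("algorithm configs round-trip through YAML", {
  specs <- builtin_algorithm_specs()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_algorithm_config(specs, path)
  back <- read_algorithm_config(path)
  expect_identical(names(back), names(specs))
  for (id in names(specs)) {
    expect_equal(unclass(back[[id]]), unclass(specs[[id]]))
  }
})

test_that("denominators nest in k and era universes partition, patient-wise", {
  res <- run_pipeline(sim_config = simulation_config(n_patients = 200L, seed = 13L),
                      quiet = TRUE)
  out <- res$outcomes
  den <- function(id) out$patient_id[out$algorithm_id == id & out$in_denominator]
  expect_true(all(den("1b") %in% den("1a")))
  expect_true(all(den("1c") %in% den("1b")))
  # criteria-met dates are monotone in k for patients meeting both
  o1 <- out[out$algorithm_id == "1a" & out$in_denominator, ]
  o2 <- out[out$algorithm_id == "1b" & out$in_denominator, ]
  shared <- intersect(o1$patient_id, o2$patient_id)
  expect_true(all(
    o2$criteria_met_date[match(shared, o2$patient_id)] >=
      o1$criteria_met_date[match(shared, o1$patient_id)]
  ))
  # era universes partition the overall universe
  expect_setequal(c(den("2a"), den("3a")), den("1a"))
  expect_length(intersect(den("2a"), den("3a")), 0)
  expect_setequal(c(den("2b"), den("2c")), den("2a"))
  expect_setequal(c(den("3b"), den("3c")), den("3a"))
})

test_that("the engine agrees with the brute-force scan on random patients", {
  set.seed(101)
  codesets <- hiv_codesets()
  specs <- builtin_algorithm_specs()
  demo <- data.frame(patient_id = "pX", birth_date = as.Date("1980-01-01"),
                     death_date = as.Date(NA), race_ethnicity = "Unknown",
                     stringsAsFactors = FALSE)
  for (i in 1:150) {
    p <- random_patient()
    fu <- data.frame(patient_id = "pX", entry = p$entry, exit = p$exit,
                     exit_reason = "admin_end", stringsAsFactors = FALSE)
    idx <- find_index_events(p$claims, fu, codesets$all_hiv, demo)
    if (nrow(idx) == 0) next
    got <- evaluate_algorithms(specs, p$claims, idx, fu, codesets)
    for (id in names(specs)) {
      spec <- specs[[id]]
      row <- got[got$algorithm_id == id, ]
      if (!eligible(spec, idx$first_hiv_code_date)) {
        expect_identical(nrow(row), 0L)
        next
      }
      want <- oracle_evaluate(spec, p$claims, p$entry, p$exit, codesets)
      expect_identical(row$in_denominator, want$met)
      expect_identical(row$criteria_met_date, want$criteria_met_date)
    }
  }
})

test_that("evaluating with an unknown code set id errors", {
  spec <- algorithm_spec("x", "bad", "no_such_set", 1L)
  sim <- simulate_cohort(simulation_config(n_patients = 5L, seed = 1L))
  fu <- build_followup(merge_spans(sim$enrollment), sim$demographics)
  idx <- find_index_events(sim$claims, fu, hiv_codesets()$all_hiv,
                           sim$demographics)
  expect_error(evaluate_algorithms(spec, sim$claims, idx, fu),
               "unknown code set")
})
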