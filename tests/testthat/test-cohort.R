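demo_row <- function(pid, birth = "1975-06-01", death = NA) {
  data.frame(patient_id = pid, birth_date = as.Date(birth),
             death_date = as.Date(death), race_ethnicity = "Unknown",
             stringsAsFactors = FALSE)
}

span <- function(pid, start, end) {
  data.frame(patient_id = pid, start = as.Date(start), end = as.Date(end),
             stringsAsFactors = FALSE)
}

test_that("continuous enrollment runs to administrative study end", {
  fu <- build_followup(span("p1", "2010-01-01", "2020-12-31"), demo_row("p1"))
  expect_identical(fu$entry, as.Date("2010-01-01"))
  expect_identical(fu$exit, as.Date("2020-12-31"))
  expect_identical(fu$exit_reason, "admin_end")
})

test_that("a gap strictly over 90 days censors at the last covered day; 90 days does not", {
  # 106-day gap: censored at the day the first span ends, no re-entry
  enr <- rbind(span("p1", "2010-01-01", "2015-06-30"),
               span("p1", "2015-10-15", "2020-12-31"))
  fu <- build_followup(enr, demo_row("p1"))
  expect_identical(fu$exit, as.Date("2015-06-30"))
  expect_identical(fu$exit_reason, "disenrollment_or_pcp_gap")
  expect_identical(nrow(fu), 1L)

  # exactly 90 uncovered days: bridged, follow-up continues
  enr90 <- rbind(span("p2", "2010-01-01", "2015-06-30"),
                 span("p2", "2015-09-29", "2020-12-31"))
  fu90 <- build_followup(enr90, demo_row("p2"))
  expect_identical(fu90$exit, as.Date("2020-12-31"))
  expect_identical(fu90$exit_reason, "admin_end")

  # 91 uncovered days: censored
  enr91 <- rbind(span("p3", "2010-01-01", "2015-06-30"),
                 span("p3", "2015-09-30", "2020-12-31"))
  fu91 <- build_followup(enr91, demo_row("p3"))
  expect_identical(fu91$exit, as.Date("2015-06-30"))
})

test_that("death, residency gaps and age 90 censor correctly", {
  fu <- build_followup(span("p1", "2010-01-01", "2020-12-31"),
                       demo_row("p1", death = "2018-02-01"))
  expect_identical(fu$exit, as.Date("2018-02-01"))
  expect_identical(fu$exit_reason, "death")

  fu_res <- build_followup(
    span("p2", "2010-01-01", "2020-12-31"), demo_row("p2"),
    residency = span("p2", "2010-01-01", "2014-03-01")
  )
  expect_identical(fu_res$exit, as.Date("2014-03-01"))
  expect_identical(fu_res$exit_reason, "residency_gap")

  # born 1928-06-15: 90th birthday 2018-06-15, censored the day before
  fu_age <- build_followup(span("p3", "2010-01-01", "2020-12-31"),
                           demo_row("p3", birth = "1928-06-15"))
  expect_identical(fu_age$exit, as.Date("2018-06-14"))
  expect_identical(fu_age$exit_reason, "age_90")
})

test_that("patients without eligible follow-up are excluded with a message", {
  enr <- rbind(span("p1", "2000-01-01", "2005-01-01"), # ends before study
               span("p2", "2010-01-01", "2020-12-31"))
  demo <- rbind(demo_row("p1"), demo_row("p2"))
  expect_message(fu <- build_followup(enr, demo), "excluded 1 patient")
  expect_identical(fu$patient_id, "p2")
})

test_that("follow-up length is nonnegative and reasons partition the cohort", {
  sim <- simulate_cohort(simulation_config(n_patients = 120L, seed = 5L))
  fu <- build_followup(merge_spans(sim$enrollment), sim$demographics,
                       merge_spans(sim$residency))
  expect_true(all(fu$exit >= fu$entry))
  expect_true(all(fu$exit <= as.Date("2020-12-31")))
  expect_identical(sum(table(fu$exit_reason)), nrow(fu))
  expect_identical(anyDuplicated(fu$patient_id), 0L)
})

test_that("index events take the first HIV code day inside follow-up", {
  sets <- hiv_codesets()
  fu <- build_followup(span("p1", "2012-01-01", "2020-12-31"), demo_row("p1"))
  df <- claims(
    patient_id = rep("p1", 3),
    service_date = as.Date(c("2011-05-01", "2014-05-01", "2016-01-01")),
    system = c("ICD9CM-DX", "ICD9CM-DX", "ICD10CM-DX"),
    code = c("042", "042", "B20"),
    setting = "outpatient"
  )
  idx <- find_index_events(df, fu, sets$all_hiv, demo_row("p1"))
  # pre-entry code ignored; earliest in-follow-up code wins
  expect_identical(idx$first_hiv_code_date, as.Date("2014-05-01"))
  expect_identical(idx$era_at_index, "ICD9_ERA")
  expect_identical(idx$age_at_index, 38L)

  # only code after exit: absent from output
  fu2 <- build_followup(span("p2", "2010-01-01", "2013-12-31"), demo_row("p2"))
  df2 <- claims("p2", as.Date("2016-01-01"), "ICD10CM-DX", "B20", "outpatient")
  expect_identical(nrow(find_index_events(df2, fu2, sets$all_hiv, demo_row("p2"))), 0L)
})

test_that("insurance at index uses the covering interval, later start winning ties", {
  ins <- data.frame(
    patient_id = "p1",
    start = as.Date(c("2010-01-01", "2014-05-01", "2014-05-01")),
    payer = c("commercial", "Medicaid", "Medicare"),
    stringsAsFactors = FALSE
  )
  expect_identical(insurance_at(ins, "p1", as.Date("2012-01-01")), "commercial")
  expect_identical(insurance_at(ins, "p1", as.Date("2014-05-01")), "Medicare")
  expect_identical(insurance_at(ins, "p1", as.Date("2009-01-01")), NA_character_)
})

test_that("index events partition by era across a simulated cohort", {
  sim <- simulate_cohort(simulation_config(n_patients = 150L, seed = 9L))
  fu <- build_followup(merge_spans(sim$enrollment), sim$demographics,
                       merge_spans(sim$residency))
  idx <- find_index_events(sim$claims, fu, hiv_codesets()$all_hiv,
                           sim$demographics, sim$insurance)
  expect_identical(
    sum(idx$era_at_index == "ICD9_ERA") + sum(idx$era_at_index == "ICD10_ERA"),
    nrow(idx)
  )
  expect_identical(nrow(idx), 150L) # every generated patient indexes
})
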