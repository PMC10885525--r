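# Synthetic claims/enrollment/demographics/chart-review generator with
# known per-patient ground truth. Emulates a 2010-2020 cohort of women
# health-plan enrollees spanning the ICD-9-CM to ICD-10-CM transition:
# every generated patient has at least one HIV diagnosis code day in
# follow-up (the validation universe is code-positive women), a latent
# truly-HIV status, era-appropriate code vocabulary, CD4 procedure days,
# and chart-review records consistent with the adjudication rules.

#' Simulation configuration
#'
#' Defaults constitute the calibration preset: a 272-woman cohort whose
#' expected marginals approximate the validation study being emulated —
#' roughly 80% of code-positive women confirmable at the first code day,
#' true cases very likely to re-code (so first-code PPV is markedly lower
#' than second-code PPV), an index-era split of about 51/49 between the
#' ICD-9 and ICD-10 eras, and 98.7% of confirmations via clinician note.
#'
#' Truth is latent per patient, not per claim: a `truly_hiv` flag plus a
#' true diagnosis date. Code days before the true diagnosis date cannot be
#' chart-confirmed, which is what makes the first-code PPV lower than the
#' later-code PPVs.
#'
#' @param n_patients cohort size (default 272).
#' @param study_start,study_end study window.
#' @param era_break first day of the ICD-10-CM era.
#' @param prevalence_true_given_coded probability a code-positive patient is
#'   truly HIV-positive.
#' @param p_truth_after_first_code among true cases, probability the first
#'   code day *precedes* the true diagnosis date (a premature code that the
#'   chart cannot confirm); the diagnosis then dates to the second code day.
#' @param mean_code_days_true mean total HIV code days for a true case
#'   (must exceed 1; count is `1 + Poisson(mean - 1)`).
#' @param p_extra_code_day_false probability governing extra code days for
#'   false positives (count is `1 + Binomial(2, p)`; miscodes are usually
#'   isolated).
#' @param mean_code_gap_days mean gap in days between successive code days.
#' @param code_weights_icd9,code_weights_icd10 named per-era sampling
#'   weights over the individual diagnosis codes (the ICD-10 `"O98"` entry
#'   stands for the pregnancy/childbirth/puerperium group; a uniform draw
#'   over its six codes). Each vector must sum to 1.
#' @param p_icd9_index probability the index (first) code day falls in the
#'   ICD-9-CM era.
#' @param cd4_rate_true,cd4_rate_false probability of at least one CD4
#'   procedure-code day on/after the index date, by true status.
#' @param p_note_evidence probability a confirmation is evidenced by a
#'   clinician note rather than laboratory results (default 0.987).
#' @param p_viral_load_given_lab split of laboratory evidence between viral
#'   load and antibody testing.
#' @param followup_meanlog,followup_sdlog log-normal parameters for years
#'   of follow-up after the index date (defaults give median 2.0 years,
#'   IQR roughly 0.9-4.2).
#' @param exit_weights named weights for the exit reason when follow-up
#'   ends before the study does (`disenrollment_or_pcp_gap`, `death`,
#'   `residency_gap`).
#' @param max_enrollment_lead_years maximum enrollment time before index.
#' @param age_meanlog,age_sdlog log-normal parameters for age at index
#'   (defaults give median 40, IQR roughly 32-49), truncated to 18-89.
#' @param race_weights,insurance_weights cosmetic demographic marginals;
#'   they play no role in any computation.
#' @param seed integer seed; the generator is fully deterministic given the
#'   seed, and per-patient random streams are split by patient index so
#'   enlarging the cohort never perturbs existing patients.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_patients = 272L,
    study_start = as.Date("2010-01-01"),
    study_end = as.Date("2020-12-31"),
    era_break = as.Date("2015-10-01"),
    prevalence_true_given_coded = 0.835,
    p_truth_after_first_code = 0.04,
    mean_code_days_true = 5,
    p_extra_code_day_false = 0.15,
    mean_code_gap_days = 120,
    code_weights_icd9 = c("042" = 0.50, "V08" = 0.47, "07953" = 0.01,
                          "79571" = 0.02),
    code_weights_icd10 = c("B20" = 0.52, "Z21" = 0.45, "B9735" = 0,
                           "O98" = 0.03),
    p_icd9_index = 0.51,
    cd4_rate_true = 0.92,
    cd4_rate_false = 0.12,
    p_note_evidence = 0.987,
    p_viral_load_given_lab = 0.5,
    followup_meanlog = log(2.0), followup_sdlog = 1.1,
    exit_weights = c(disenrollment_or_pcp_gap = 0.89, death = 0.062,
                     residency_gap = 0.048),
    max_enrollment_lead_years = 3,
    age_meanlog = log(40), age_sdlog = 0.30,
    race_weights = c("Hispanic" = 24, "Native American/Alaska Native" = 0,
                     "Non-Hispanic Black" = 98, "Non-Hispanic White" = 89,
                     "Multiple Races/Other Race" = 19, "Unknown" = 42),
    insurance_weights = c(Medicaid = 0.055, Medicare = 0.077,
                          commercial = 0.868),
    seed = 20100101L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    study_start = as_date_strict(study_start, "study_start"),
    study_end = as_date_strict(study_end, "study_end"),
    era_break = as_date_strict(era_break, "era_break"),
    prevalence_true_given_coded = prevalence_true_given_coded,
    p_truth_after_first_code = p_truth_after_first_code,
    mean_code_days_true = mean_code_days_true,
    p_extra_code_day_false = p_extra_code_day_false,
    mean_code_gap_days = mean_code_gap_days,
    code_weights_icd9 = code_weights_icd9,
    code_weights_icd10 = code_weights_icd10,
    p_icd9_index = p_icd9_index,
    cd4_rate_true = cd4_rate_true,
    cd4_rate_false = cd4_rate_false,
    p_note_evidence = p_note_evidence,
    p_viral_load_given_lab = p_viral_load_given_lab,
    followup_meanlog = followup_meanlog, followup_sdlog = followup_sdlog,
    exit_weights = exit_weights,
    max_enrollment_lead_years = max_enrollment_lead_years,
    age_meanlog = age_meanlog, age_sdlog = age_sdlog,
    race_weights = race_weights,
    insurance_weights = insurance_weights,
    seed = as.integer(seed)
  )
  probs <- c(
    prevalence_true_given_coded = cfg$prevalence_true_given_coded,
    p_truth_after_first_code = cfg$p_truth_after_first_code,
    p_extra_code_day_false = cfg$p_extra_code_day_false,
    p_icd9_index = cfg$p_icd9_index,
    cd4_rate_true = cfg$cd4_rate_true,
    cd4_rate_false = cfg$cd4_rate_false,
    p_note_evidence = cfg$p_note_evidence,
    p_viral_load_given_lab = cfg$p_viral_load_given_lab
  )
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    stop(sprintf("probability parameter(s) outside [0,1]: %s",
                 paste(names(probs)[bad], collapse = ", ")), call. = FALSE)
  }
  for (w in c("code_weights_icd9", "code_weights_icd10")) {
    if (abs(sum(cfg[[w]]) - 1) > 1e-8 || any(cfg[[w]] < 0)) {
      stop(sprintf("%s must be nonnegative and sum to 1", w), call. = FALSE)
    }
  }
  if (cfg$n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  if (cfg$mean_code_days_true <= 1) {
    stop("mean_code_days_true must exceed 1", call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

#' The calibration preset
#'
#' The [simulation_config()] defaults as an explicit preset: a 272-patient
#' cohort calibrated to the validation-study marginals.
#'
#' @param ... overrides passed to [simulation_config()].
#' @return a `simulation_config`.
#' @export
calibration_preset <- function(...) {
  simulation_config(...)
}

#' Expected first-code-day PPV implied by a configuration
#'
#' The configured probability that a code-positive patient is chart
#' confirmable as of their first code day: truly HIV and not carrying a
#' premature first code. The empirical PPV of the ">= 1 code day" algorithm
#' converges to (approximately) this value as the cohort grows; the
#' approximation error is the small fraction of premature-first-code cases
#' whose confirming second code day never materialises inside follow-up.
#'
#' @param config a [simulation_config()].
#' @return expected PPV on the percent scale.
#' @export
configured_first_code_ppv <- function(config) {
  100 * config$prevalence_true_given_coded *
    (1 - config$p_truth_after_first_code)
}

#' @noRd
patient_seed <- function(seed, i) {
  (as.double(seed) + as.double(i) * 104729) %% 2147483647
}

#' @noRd
draw_code <- function(weights, o98_codes) {
  nm <- sample(names(weights), 1L, prob = weights)
  if (nm == "O98") sample(o98_codes, 1L) else nm
}

# One patient's complete record. Draws run in a patient-specific RNG stream.
#' @noRd
simulate_patient <- function(i, cfg) {
  set.seed(patient_seed(cfg$seed, i))
  pid <- sprintf("P%05d", i)
  icd9_end <- cfg$era_break - 1L
  o98 <- c("O98711", "O98712", "O98713", "O98719", "O9872", "O9873")

  # index day (first HIV code day), era-stratified
  in_icd9 <- stats::runif(1) < cfg$p_icd9_index
  index <- if (in_icd9) {
    cfg$study_start + floor(stats::runif(1) *
                              (as.integer(icd9_end - cfg$study_start) + 1L))
  } else {
    cfg$era_break + floor(stats::runif(1) *
                            (as.integer(cfg$study_end - cfg$era_break) + 1L))
  }

  age <- min(89L, max(18L, as.integer(round(stats::rlnorm(
    1, cfg$age_meanlog, cfg$age_sdlog
  )))))
  birth <- add_years(index, -(age + 1L)) + 1L +
    floor(stats::runif(1) * 364)
  # keep the drawn completed-years age exact at index
  if (age_at(birth, index) != age) {
    birth <- add_years(index, -age)
  }

  truly_hiv <- stats::runif(1) < cfg$prevalence_true_given_coded

  # follow-up after index, and the exit reason realised in the coverage data
  dur_days <- max(0L, as.integer(round(
    stats::rlnorm(1, cfg$followup_meanlog, cfg$followup_sdlog) * 365.25
  )))
  exit_cand <- index + dur_days
  age90_exit <- add_years(birth, 90L) - 1L
  if (exit_cand >= cfg$study_end && cfg$study_end <= age90_exit) {
    exit <- cfg$study_end
    reason <- "admin_end"
  } else if (age90_exit < exit_cand) {
    exit <- age90_exit
    reason <- "age_90"
  } else {
    reason <- sample(names(cfg$exit_weights), 1L, prob = cfg$exit_weights)
    exit <- exit_cand
    # a pre-study-end gap must be observable as > 90 days; exits too close
    # to the study end are administratively censored instead
    if (reason != "death" && as.integer(cfg$study_end - exit) <= 90L) {
      exit <- cfg$study_end
      reason <- "admin_end"
    }
  }

  entry <- max(cfg$study_start, add_years(birth, 18L),
               index - as.integer(round(
                 stats::runif(1, 0, cfg$max_enrollment_lead_years) * 365.25
               )))

  # HIV code days: index plus later recurrences inside follow-up
  n_days <- if (truly_hiv) {
    1L + stats::rpois(1, cfg$mean_code_days_true - 1)
  } else {
    1L + stats::rbinom(1, 2L, cfg$p_extra_code_day_false)
  }
  gaps <- if (n_days > 1L) {
    1L + stats::rpois(n_days - 1L, cfg$mean_code_gap_days - 1)
  } else {
    integer(0)
  }
  code_days <- index + cumsum(c(0L, gaps))
  code_days <- code_days[code_days <= exit]

  true_dx <- as.Date(NA)
  if (truly_hiv) {
    premature <- stats::runif(1) < cfg$p_truth_after_first_code
    true_dx <- if (!premature) {
      code_days[1]
    } else if (length(code_days) >= 2L) {
      code_days[2]
    } else {
      code_days[1] + 1L # never confirmable: sole code predates the diagnosis
    }
  }

  hiv_rows <- data.frame(
    patient_id = pid,
    service_date = code_days,
    system = ifelse(code_days <= icd9_end, "ICD9CM-DX", "ICD10CM-DX"),
    code = vapply(seq_along(code_days), function(k) {
      if (code_days[k] <= icd9_end) {
        draw_code(cfg$code_weights_icd9, o98)
      } else {
        draw_code(cfg$code_weights_icd10, o98)
      }
    }, ""),
    setting = sample(c("outpatient", "inpatient"), length(code_days),
                     replace = TRUE, prob = c(0.9, 0.1)),
    stringsAsFactors = FALSE
  )

  cd4_rate <- if (truly_hiv) cfg$cd4_rate_true else cfg$cd4_rate_false
  cd4_days <- as.Date(integer(0))
  if (stats::runif(1) < cd4_rate) {
    cd4_days <- index + sort(unique(as.integer(round(
      stats::runif(1L + stats::rbinom(1, 1, 0.5), 0, 120)
    ))))
    cd4_days <- cd4_days[cd4_days <= exit]
  }
  # occasional pre-index CD4 testing, which companion clauses must ignore
  if (stats::runif(1) < 0.10 && index - 60L >= entry) {
    cd4_days <- sort(c(index - as.integer(round(stats::runif(1, 10, 60))),
                       cd4_days))
  }
  cd4_rows <- if (length(cd4_days)) {
    data.frame(
      patient_id = pid, service_date = cd4_days, system = "CPT",
      code = sample(c("86360", "86361"), length(cd4_days), replace = TRUE),
      setting = "outpatient", stringsAsFactors = FALSE
    )
  }

  # chart review: chronological, stopping at the first confirmation
  chart <- NULL
  for (d in seq_along(code_days)) {
    day <- code_days[d]
    confirms <- truly_hiv && !is.na(true_dx) && day >= true_dx
    if (confirms) {
      ev <- if (stats::runif(1) < cfg$p_note_evidence) {
        "clinician_note"
      } else if (stats::runif(1) < cfg$p_viral_load_given_lab) {
        "lab_viral_load"
      } else {
        "lab_antibody"
      }
      chart <- rbind(chart, data.frame(
        patient_id = pid, target_code_date = day, confirmed = TRUE,
        evidence = ev,
        evidence_date = day + as.integer(round(stats::runif(1, -30, 30))),
        stringsAsFactors = FALSE
      ))
      break
    }
    chart <- rbind(chart, data.frame(
      patient_id = pid, target_code_date = day, confirmed = FALSE,
      evidence = "none", evidence_date = as.Date(NA),
      stringsAsFactors = FALSE
    ))
  }

  # coverage spans realising the chosen exit reason
  # enrollment is only cut short for the disenrollment exit; for deaths the
  # coverage record runs on so that death (same exit date) is the rule that
  # fires first under the tie-break order
  enr_end <- if (reason == "disenrollment_or_pcp_gap") exit else cfg$study_end
  res_end <- if (reason == "residency_gap") exit else cfg$study_end

  list(
    claims = rbind(hiv_rows, cd4_rows),
    enrollment = data.frame(patient_id = pid, start = entry, end = enr_end,
                            stringsAsFactors = FALSE),
    residency = data.frame(patient_id = pid, start = entry, end = res_end,
                           stringsAsFactors = FALSE),
    demographics = data.frame(
      patient_id = pid, birth_date = birth,
      death_date = if (reason == "death") exit else as.Date(NA),
      race_ethnicity = sample(names(cfg$race_weights), 1L,
                              prob = cfg$race_weights),
      stringsAsFactors = FALSE
    ),
    insurance = data.frame(
      patient_id = pid, start = cfg$study_start,
      payer = sample(names(cfg$insurance_weights), 1L,
                     prob = cfg$insurance_weights),
      stringsAsFactors = FALSE
    ),
    chart_reviews = chart,
    ground_truth = data.frame(
      patient_id = pid, truly_hiv = truly_hiv, true_diagnosis_date = true_dx,
      stringsAsFactors = FALSE
    )
  )
}

#' Generate a complete synthetic validation dataset
#'
#' Fully deterministic given `config$seed` (per-patient streams are split by
#' patient index, so increasing `n_patients` reproduces the original
#' patients exactly and appends new ones). Every patient has at least one
#' HIV diagnosis code day inside their follow-up; truly-HIV patients draw
#' recurring code days with era-appropriate vocabulary and frequent CD4
#' procedure days; false positives draw mostly isolated code days and chart
#' records that never confirm; a true case's chart confirms at the first
#' reviewed code day on or after the latent true diagnosis date.
#'
#' @param config a [simulation_config()].
#' @return list of data frames: `claims`, `enrollment`, `residency`,
#'   `demographics`, `insurance`, `chart_reviews`, `ground_truth`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  parts <- lapply(seq_len(config$n_patients), simulate_patient, cfg = config)
  bind <- function(name) {
    out <- do.call(rbind, lapply(parts, `[[`, name))
    rownames(out) <- NULL
    out
  }
  list(
    claims = bind("claims"),
    enrollment = bind("enrollment"),
    residency = bind("residency"),
    demographics = bind("demographics"),
    insurance = bind("insurance"),
    chart_reviews = bind("chart_reviews"),
    ground_truth = bind("ground_truth")
  )
}

#' Write a simulated dataset as the pipeline's CSV inputs
#'
#' @param sim output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(claims = "claims.csv", enrollment = "enrollment.csv",
             residency = "residency.csv", demographics = "demographics.csv",
             insurance = "insurance.csv", chart_reviews = "chart_reviews.csv",
             ground_truth = "ground_truth.csv")
  for (nm in names(files)) {
    write_table(sim[[nm]], file.path(dir, files[[nm]]))
  }
  invisible(dir)
}
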