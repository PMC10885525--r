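# Pipeline driver and reporting: cohort descriptive statistics, the
# validation table, a printed-counts mode, and an end-to-end runner.

#' Descriptive statistics for the code-positive cohort
#'
#' Summarises the indexed cohort: age at index (mean/SD, median/IQR and
#' category counts), race/ethnicity counts (percentages computed after
#' excluding unknowns), insurance at index, index-period counts, follow-up
#' duration in years from the index code day to cohort exit (mean/SD,
#' median/IQR — 25th/75th percentiles with linear interpolation — and
#' categories), and exit-reason counts.
#'
#' @param index_events output of [find_index_events()].
#' @param followups output of [build_followup()].
#' @param demographics demographics data frame.
#' @param era_split_year first calendar year of the later index period
#'   (default 2015, i.e. periods 2010–2014 and 2015–2020).
#' @return a list of class `cohort_summary`.
#' @export
describe_cohort <- function(index_events, followups, demographics,
                            era_split_year = 2015L) {
  if (nrow(index_events) == 0) {
    stop("cannot describe an empty cohort", call. = FALSE)
  }
  n <- nrow(index_events)
  fu <- followups[match(index_events$patient_id, followups$patient_id), ]
  demo <- demographics[match(index_events$patient_id, demographics$patient_id), ]

  age <- index_events$age_at_index
  age_cat <- cut(age, breaks = c(17, 29, 39, 49, 59, 89),
                 labels = c("18-29", "30-39", "40-49", "50-59", "60-89"))
  dur_years <- as.numeric(fu$exit - index_events$first_hiv_code_date) / 365.25
  dur_cat <- cut(dur_years, breaks = c(-Inf, 1, 3, 5, Inf), right = FALSE,
                 labels = c("0 to <1", "1 to <3", "3 to <5", ">=5"))

  race <- demo$race_ethnicity
  known <- race[!is.na(race) & race != "Unknown"]
  race_counts <- table(factor(race, exclude = NULL))
  race_pct <- if (length(known)) {
    round_half_up(100 * table(known) / length(known), 1)
  } else {
    NULL # all unknown: percentages not estimable
  }

  idx_year <- as.integer(format(index_events$first_hiv_code_date, "%Y"))
  period <- ifelse(idx_year < era_split_year,
                   sprintf("%d-%d", min(idx_year), era_split_year - 1L),
                   sprintf("%d-%d", era_split_year, max(idx_year)))

  quart <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), type = 7,
                                       names = FALSE)
  aq <- quart(age)
  dq <- quart(dur_years)
  structure(list(
    n = n,
    age = list(mean = mean(age), sd = stats::sd(age),
               median = aq[2], q1 = aq[1], q3 = aq[3],
               categories = as.list(table(age_cat))),
    race_ethnicity = list(counts = as.list(race_counts),
                          pct_known = as.list(race_pct),
                          n_unknown = sum(is.na(race) | race == "Unknown")),
    insurance = as.list(table(index_events$insurance_at_index, useNA = "ifany")),
    index_period = as.list(table(period)),
    followup_years = list(mean = mean(dur_years), sd = stats::sd(dur_years),
                          median = dq[2], q1 = dq[1], q3 = dq[3],
                          categories = as.list(table(dur_cat))),
    exit_reasons = as.list(table(fu$exit_reason))
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d code-positive patients\n", x$n))
  cat(sprintf("  Age at index: mean %.1f (SD %.1f), median %g (IQR %g-%g)\n",
              x$age$mean, x$age$sd, x$age$median, x$age$q1, x$age$q3))
  cat(sprintf("  Follow-up years: mean %.1f (SD %.1f), median %.1f (IQR %.1f-%.1f)\n",
              x$followup_years$mean, x$followup_years$sd,
              x$followup_years$median, x$followup_years$q1,
              x$followup_years$q3))
  cat("  Exit reasons:",
      paste(sprintf("%s=%s", names(x$exit_reasons), unlist(x$exit_reasons)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Printed-counts mode: validation cells from a table of counts
#'
#' Computes PPVs and Wilson intervals directly from per-algorithm `(N, n)`
#' counts — for example a published validation table — with no raw
#' patient-level data. This decouples checking the statistical machinery
#' from the simulation.
#'
#' @param counts data frame with columns `algorithm_id`, `N`, `n` and
#'   optionally `label`.
#' @param conf_level confidence level.
#' @return validation-cell data frame (see [validation_cell()]).
#' @export
evaluate_counts <- function(counts, conf_level = 0.95) {
  check_columns(counts, c("algorithm_id", "N", "n"), "counts")
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    validation_cell(
      counts$algorithm_id[i], as.integer(counts$N[i]), as.integer(counts$n[i]),
      conf_level = conf_level,
      label = if ("label" %in% names(counts)) counts$label[i] else NA_character_
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full validation pipeline
#'
#' Executes read (or simulate) → follow-up → index events → gold-standard
#' adjudication → algorithm evaluation → validation table → descriptive
#' summary, logging row counts at each stage. Identical inputs (or an
#' identical simulation seed) yield identical outputs.
#'
#' @param input_dir directory containing `claims.csv`, `enrollment.csv`,
#'   `demographics.csv`, `insurance.csv`, `chart_reviews.csv` and
#'   optionally `residency.csv`; ignored when `sim_config` is given.
#' @param sim_config optional [simulation_config()]; when supplied the
#'   inputs are generated in memory instead of read from disk.
#' @param out_dir optional directory to write `validation_table.csv`,
#'   `confirmations.csv`, `outcomes.csv`, `followup.csv`, `index.csv`,
#'   `cohort_summary.json` and `validation_table.md`.
#' @param specs algorithm suite (default [builtin_algorithm_specs()]).
#' @param codesets code-set collection (default [hiv_codesets()]).
#' @param calendar an [era_calendar()].
#' @param followup_cfg a [followup_config()].
#' @param window_days chart-review window half-width.
#' @param quiet suppress stage logging.
#' @return list with `validation_table`, `cohort_summary`, `followups`,
#'   `index_events`, `confirmations`, `outcomes` (and `sim` when simulated).
#' @export
run_pipeline <- function(input_dir = NULL, sim_config = NULL, out_dir = NULL,
                         specs = NULL, codesets = hiv_codesets(),
                         calendar = era_calendar(),
                         followup_cfg = NULL, window_days = 183L,
                         quiet = FALSE) {
  log <- function(...) if (!quiet) message(sprintf(...))
  if (is.null(followup_cfg)) {
    followup_cfg <- followup_config(study_start = calendar$icd9_start,
                                    study_end = calendar$study_end)
  }
  if (is.null(specs)) specs <- builtin_algorithm_specs(calendar)

  if (!is.null(sim_config)) {
    log("stage simulate: %d patients, seed %d",
        sim_config$n_patients, sim_config$seed)
    sim <- simulate_cohort(sim_config)
    claims_df <- sim$claims
    enrollment <- merge_spans(sim$enrollment)
    residency <- merge_spans(sim$residency)
    demographics <- sim$demographics
    insurance <- sim$insurance
    chart_reviews <- sim$chart_reviews
  } else {
    if (is.null(input_dir)) {
      stop("either input_dir or sim_config must be supplied", call. = FALSE)
    }
    p <- function(f) file.path(input_dir, f)
    claims_df <- read_claims(p("claims.csv"), calendar = calendar)
    enrollment <- read_enrollment(p("enrollment.csv"))
    demographics <- read_demographics(p("demographics.csv"))
    insurance <- read_insurance(p("insurance.csv"))
    chart_reviews <- read_chart_reviews(p("chart_reviews.csv"))
    residency <- if (file.exists(p("residency.csv"))) {
      read_residency(p("residency.csv"))
    }
    sim <- NULL
    log("stage read: %d claims, %d enrollment spans, %d patients",
        nrow(claims_df), nrow(enrollment), nrow(demographics))
  }

  followups <- build_followup(enrollment, demographics, residency,
                              followup_cfg)
  log("stage cohort: %d follow-up records", nrow(followups))

  index_events <- find_index_events(claims_df, followups, codesets$all_hiv,
                                    demographics, insurance, calendar)
  log("stage index: %d patients with an HIV code day in follow-up",
      nrow(index_events))

  confirmations <- adjudicate_all(claims_df, followups, index_events,
                                  chart_reviews, codesets$all_hiv,
                                  window_days)
  log("stage adjudicate: %d confirmed of %d reviewed",
      sum(confirmations$confirmed), nrow(confirmations))

  outcomes <- evaluate_algorithms(specs, claims_df, index_events, followups,
                                  codesets)
  log("stage evaluate: %d algorithm outcomes across %d algorithms",
      nrow(outcomes), length(specs))

  cells <- validation_table(outcomes, confirmations, specs)
  summary <- describe_cohort(index_events, followups, demographics)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_table(cells, file.path(out_dir, "validation_table.csv"))
    write_table(confirmations, file.path(out_dir, "confirmations.csv"))
    write_table(outcomes, file.path(out_dir, "outcomes.csv"))
    write_table(followups, file.path(out_dir, "followup.csv"))
    write_table(index_events, file.path(out_dir, "index.csv"))
    jsonlite::write_json(unclass(summary),
                         file.path(out_dir, "cohort_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    writeLines(render_validation_table(cells),
               file.path(out_dir, "validation_table.md"))
    log("stage report: outputs written to %s", out_dir)
  }

  out <- list(validation_table = cells, cohort_summary = summary,
              followups = followups, index_events = index_events,
              confirmations = confirmations, outcomes = outcomes)
  if (!is.null(sim)) out$sim <- sim
  out
}
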