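# Independent brute-force reference implementations used to cross-check the
# rule engine and the adjudicator, plus a generator of small random
# patients. The oracles deliberately avoid the package's evaluation paths:
# they scan all claims, all candidate dates and all chart records with no
# early termination.

# Distinct qualifying days by per-claim linear scan.
oracle_code_days <- function(claim_rows, set, from, to, window = NULL) {
  keys <- paste(set$elements$system, set$elements$code)
  days <- as.Date(character(0))
  for (i in seq_len(nrow(claim_rows))) {
    d <- claim_rows$service_date[i]
    if (!(paste(claim_rows$system[i], claim_rows$code[i]) %in% keys)) next
    if (d < from || d > to) next
    if (!is.null(window) && (d < window[1] || d > window[2])) next
    if (!(d %in% days)) days <- c(days, d)
  }
  sort(days)
}

# Criteria-met date by scanning every candidate date in increasing order.
oracle_evaluate <- function(spec, claim_rows, from, to, codesets) {
  prim <- oracle_code_days(claim_rows, codesets[[spec$code_set_id]],
                           from, to, spec$window)
  comp <- if (!is.null(spec$companion_code_set_id)) {
    oracle_code_days(claim_rows, codesets[[spec$companion_code_set_id]],
                     from, to)
  } else {
    as.Date(character(0))
  }
  candidates <- sort(unique(c(prim, comp)))
  for (t in as.list(candidates)) {
    n_prim <- sum(prim <= t)
    if (n_prim < spec$min_distinct_days) next
    if (!is.null(spec$companion_code_set_id)) {
      if (!any(comp >= prim[1] & comp <= t)) next
    }
    return(list(met = TRUE, criteria_met_date = t))
  }
  list(met = FALSE, criteria_met_date = as.Date(NA))
}

# Confirmation by exhaustive scan over all (code day, record) pairs.
oracle_adjudicate <- function(code_days, chart_records) {
  best <- as.Date(NA)
  evidence <- "none"
  for (d in as.list(code_days)) {
    for (j in seq_len(nrow(chart_records))) {
      if (chart_records$target_code_date[j] != d) next
      if (!chart_records$confirmed[j]) next
      if (is.na(best) || d < best) {
        best <- d
        evidence <- chart_records$evidence[j]
      }
    }
  }
  list(confirmed = !is.na(best), confirmation_date = best,
       evidence = evidence)
}

# A small random patient: claims (HIV + CD4), follow-up bounds, and chart
# records (one per HIV code day, random outcome). Era-consistent codes.
random_patient <- function(pid = "pX") {
  icd9_codes <- c("042", "V08", "07953", "79571")
  icd10_codes <- c("B20", "Z21", "B9735", "O98711", "O9872")
  entry <- as.Date("2010-01-01") + sample.int(2000, 1)
  exit <- entry + sample.int(2500, 1)
  exit <- min(exit, as.Date("2020-12-31"))
  n_days <- sample(0:5, 1)
  days <- sort(sample(seq(entry - 200, exit + 200, by = "day"), n_days))
  claim_rows <- NULL
  for (d in as.list(days)) {
    sys <- if (d <= as.Date("2015-09-30")) "ICD9CM-DX" else "ICD10CM-DX"
    code <- if (sys == "ICD9CM-DX") sample(icd9_codes, 1) else sample(icd10_codes, 1)
    reps <- sample(1:2, 1) # occasional duplicate claim lines on one day
    for (r in seq_len(reps)) {
      claim_rows <- rbind(claim_rows, data.frame(
        patient_id = pid, service_date = d, system = sys, code = code,
        setting = sample(c("inpatient", "outpatient"), 1),
        stringsAsFactors = FALSE
      ))
    }
  }
  n_cd4 <- sample(0:3, 1)
  if (n_cd4 > 0) {
    cd4 <- sort(sample(seq(entry - 100, exit + 100, by = "day"), n_cd4))
    claim_rows <- rbind(claim_rows, data.frame(
      patient_id = pid, service_date = cd4, system = "CPT",
      code = sample(c("86360", "86361"), n_cd4, replace = TRUE),
      setting = "outpatient", stringsAsFactors = FALSE
    ))
  }
  in_fu <- days[days >= entry & days <= exit]
  chart <- data.frame(
    patient_id = character(0), target_code_date = as.Date(character(0)),
    confirmed = logical(0), evidence = character(0),
    evidence_date = as.Date(character(0)), stringsAsFactors = FALSE
  )
  for (d in as.list(in_fu)) {
    conf <- runif(1) < 0.5
    chart <- rbind(chart, data.frame(
      patient_id = pid, target_code_date = d, confirmed = conf,
      evidence = if (conf) {
        sample(c("clinician_note", "lab_viral_load", "lab_antibody"), 1)
      } else "none",
      evidence_date = if (conf) d + sample(-183:183, 1) else as.Date(NA),
      stringsAsFactors = FALSE
    ))
  }
  if (is.null(claim_rows)) {
    claim_rows <- data.frame(
      patient_id = character(0), service_date = as.Date(character(0)),
      system = character(0), code = character(0), setting = character(0),
      stringsAsFactors = FALSE
    )
  }
  list(claims = claim_rows, entry = entry, exit = exit, chart = chart)
}
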