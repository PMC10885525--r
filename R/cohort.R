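# Cohort construction: follow-up accrual under the study's censoring rules,
# and identification of each patient's index (first) HIV code day.

EXIT_REASONS <- c("disenrollment_or_pcp_gap", "residency_gap", "age_90",
                  "death", "admin_end")

#' Follow-up configuration
#'
#' @param study_start,study_end study window (closed interval).
#' @param gap_days coverage-gap threshold in days; a gap *strictly greater*
#'   than this censors (so with the default 90, a 91-day gap censors and a
#'   90-day gap does not).
#' @param min_age,max_age eligible age range in completed years.
#' @return a list of class `followup_config`.
#' @export
followup_config <- function(study_start = as.Date("2010-01-01"),
                            study_end = as.Date("2020-12-31"),
                            gap_days = 90L,
                            min_age = 18L, max_age = 89L) {
  stopifnot(gap_days >= 0, min_age >= 0, max_age > min_age)
  structure(
    list(
      study_start = as_date_strict(study_start, "study_start"),
      study_end = as_date_strict(study_end, "study_end"),
      gap_days = as.integer(gap_days),
      min_age = as.integer(min_age),
      max_age = as.integer(max_age)
    ),
    class = "followup_config"
  )
}

# Exit date implied by gaps in one coverage stream, given entry. Walks the
# merged spans forward from entry; a between-span gap longer than the
# threshold censors at the last covered day before the gap. A trailing gap
# (after the final span, measured against study_end) censors the same way;
# a trailing gap short enough to be bridgeable at study_end does not censor.
#' @noRd
gap_exit <- function(spans, entry, cfg) {
  spans <- spans[spans$end >= entry, , drop = FALSE]
  if (nrow(spans) == 0 || spans$start[1] > entry) {
    return(NULL) # entry not covered; caller excludes the patient
  }
  spans <- spans[order(spans$start), , drop = FALSE]
  covered_until <- spans$end[1]
  if (nrow(spans) > 1) {
    for (i in 2:nrow(spans)) {
      gap <- as.integer(spans$start[i] - covered_until) - 1L
      if (gap > cfg$gap_days) {
        return(covered_until)
      }
      covered_until <- max(covered_until, spans$end[i])
    }
  }
  trailing <- as.integer(cfg$study_end - covered_until)
  if (trailing > cfg$gap_days) covered_until else NA
}

#' Build per-patient follow-up records
#'
#' Follow-up accrues from cohort entry until the earliest of: a coverage gap
#' longer than `gap_days` in enrollment (exit reason
#' `disenrollment_or_pcp_gap`), such a gap in catchment-area residency
#' (`residency_gap`), reaching age `max_age + 1` (`age_90`, censored at the
#' day before the birthday so follow-up contains only eligible days), death
#' (`death`), or the administrative end of the study (`admin_end`). Ties are
#' broken in that order. Gap censoring falls on the last covered day before
#' the gap, so follow-up never extends into uncovered time; short gaps (at
#' most `gap_days`) are bridged and the days inside them still accrue.
#' Patients never re-enter: one record per patient.
#'
#' Entry is the first day at or after `study_start` on which the patient is
#' enrolled, resident, and at least `min_age` years old. Patients with no
#' such day (or whose exit would precede entry) are excluded, with a
#' message naming them.
#'
#' @param enrollment merged enrollment spans (see [read_enrollment()]).
#' @param demographics demographics data frame (see [read_demographics()]).
#' @param residency optional merged residency spans; `NULL` means residency
#'   is never the binding constraint.
#' @param config a [followup_config()].
#' @return data frame `patient_id`, `entry`, `exit`, `exit_reason`.
#' @export
build_followup <- function(enrollment, demographics, residency = NULL,
                           config = followup_config()) {
  stopifnot(inherits(config, "followup_config"))
  demo <- demographics[match(unique(enrollment$patient_id), demographics$patient_id), ]
  if (anyNA(demo$patient_id)) {
    missing <- setdiff(unique(enrollment$patient_id), demographics$patient_id)
    stop(sprintf("no demographics for patient(s): %s",
                 paste(utils::head(missing, 5), collapse = ", ")), call. = FALSE)
  }
  enr_by <- split(enrollment, enrollment$patient_id)
  res_by <- if (!is.null(residency)) split(residency, residency$patient_id)
  excluded <- character(0)

  rows <- lapply(seq_len(nrow(demo)), function(i) {
    pid <- demo$patient_id[i]
    enr <- enr_by[[pid]]
    res <- if (!is.null(res_by)) res_by[[pid]]
    bday_min <- add_years(demo$birth_date[i], config$min_age)
    entry_cand <- max(config$study_start, bday_min, min(enr$start),
                      if (!is.null(res)) min(res$start) else config$study_start)
    # advance entry to the first day covered by both streams
    entry <- entry_cand
    repeat {
      e <- enr[enr$start <= entry & enr$end >= entry, , drop = FALSE]
      if (nrow(e) == 0) {
        nxt <- enr$start[enr$start > entry]
        if (length(nxt) == 0) return(NULL)
        entry <- min(nxt)
        next
      }
      if (!is.null(res)) {
        r <- res[res$start <= entry & res$end >= entry, , drop = FALSE]
        if (nrow(r) == 0) {
          nxt <- res$start[res$start > entry]
          if (length(nxt) == 0) return(NULL)
          entry <- min(nxt)
          next
        }
      }
      break
    }
    if (entry > config$study_end) return(NULL)

    enr_exit <- gap_exit(enr, entry, config)
    if (is.null(enr_exit)) return(NULL) # defensive: entry should be covered
    res_exit <- if (is.null(res)) NA else {
      r <- gap_exit(res, entry, config)
      if (is.null(r)) return(NULL)
      r
    }
    cand_date <- as.Date(c(
      as.numeric(enr_exit),
      as.numeric(res_exit),
      as.numeric(add_years(demo$birth_date[i], config$max_age + 1L) - 1L),
      as.numeric(demo$death_date[i]),
      as.numeric(config$study_end)
    ), origin = "1970-01-01")
    ok <- !is.na(cand_date)
    exit <- min(cand_date[ok])
    # ties broken by the order the reasons are listed
    reason <- EXIT_REASONS[ok][which(cand_date[ok] == exit)[1]]
    if (exit < entry) return(NULL)
    data.frame(patient_id = pid, entry = entry, exit = exit,
               exit_reason = reason, stringsAsFactors = FALSE)
  })
  kept <- !vapply(rows, is.null, TRUE)
  if (any(!kept)) {
    message(sprintf(
      "build_followup: excluded %d patient(s) with no eligible follow-up: %s",
      sum(!kept),
      paste(utils::head(demo$patient_id[!kept], 5), collapse = ", ")
    ))
  }
  out <- do.call(rbind, rows[kept])
  if (is.null(out)) {
    stop("no patients with eligible follow-up", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Payer covering a given date
#'
#' Insurance history is a sequence of `(start, payer)` records per patient;
#' each interval runs until the next record's start. When two records share
#' a start date the later-listed (last-sorted) one wins — a deterministic
#' tie-break.
#'
#' @param insurance insurance data frame (see [read_insurance()]).
#' @param patient_id scalar patient id.
#' @param at `Date` scalar.
#' @return payer string, or `NA_character_` if no interval covers `at`.
#' @export
insurance_at <- function(insurance, patient_id, at) {
  rec <- insurance[insurance$patient_id == patient_id &
                     insurance$start <= at, , drop = FALSE]
  if (nrow(rec) == 0) {
    return(NA_character_)
  }
  rec <- rec[order(rec$start), , drop = FALSE]
  rec$payer[nrow(rec)]
}

#' Identify index events: the first HIV code day in follow-up
#'
#' For each patient with at least one day carrying a code from `hiv_set`
#' within their follow-up interval (closed `[entry, exit]`), records that
#' first code day together with age, insurance payer and coding era at
#' index. Code days outside follow-up are ignored; patients with none inside
#' follow-up are simply absent from the result.
#'
#' @param claims claims data frame.
#' @param followups output of [build_followup()].
#' @param hiv_set the qualifying [code_set] (usually `hiv_codesets()$all_hiv`).
#' @param demographics demographics data frame (for age at index).
#' @param insurance optional insurance data frame.
#' @param calendar an [era_calendar()].
#' @return data frame `patient_id`, `first_hiv_code_date`, `age_at_index`,
#'   `insurance_at_index`, `era_at_index`.
#' @export
find_index_events <- function(claims, followups, hiv_set, demographics,
                              insurance = NULL, calendar = era_calendar()) {
  days_by <- distinct_code_days(claims, hiv_set)
  rows <- lapply(seq_len(nrow(followups)), function(i) {
    pid <- followups$patient_id[i]
    d <- days_by[[pid]]
    d <- d[d >= followups$entry[i] & d <= followups$exit[i]]
    if (length(d) == 0) return(NULL)
    idx <- d[1]
    birth <- demographics$birth_date[match(pid, demographics$patient_id)]
    data.frame(
      patient_id = pid,
      first_hiv_code_date = idx,
      age_at_index = if (!is.na(birth)) age_at(birth, idx) else NA_integer_,
      insurance_at_index = if (!is.null(insurance)) {
        insurance_at(insurance, pid, idx)
      } else NA_character_,
      era_at_index = era_of(idx, calendar),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      patient_id = character(0), first_hiv_code_date = as.Date(character(0)),
      age_at_index = integer(0), insurance_at_index = character(0),
      era_at_index = character(0), stringsAsFactors = FALSE
    )
  }
  rownames(out) <- NULL
  out
}
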