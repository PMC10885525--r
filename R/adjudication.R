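# Gold-standard adjudication: chronological chart review of diagnosis-code
# days within a +/- window, stopping at the first confirmation. The
# confirmation date is the validated code day itself (the earliest claim
# date the chart supports), not the date of the note or laboratory result.

#' Chart-review schedule for a patient's code days
#'
#' One review per code day, in chronological order, each with a closed
#' review window `[date - window_days, date + window_days]`. The plus/minus
#' six-month review window is expressed as a day count (183 by default)
#' because calendar-month arithmetic is ambiguous at month ends.
#'
#' @param code_days strictly increasing `Date` vector (possibly empty).
#' @param window_days positive integer half-width of the review window.
#' @return data frame `target_code_date`, `window_start`, `window_end`
#'   (zero rows for empty input).
#' @export
#' @examples
#' review_schedule(as.Date("2016-03-15"))
#' # window 2015-09-14 .. 2016-09-14
review_schedule <- function(code_days, window_days = 183L) {
  stopifnot(window_days > 0)
  code_days <- as_date_strict(code_days, "code day")
  if (is.unsorted(code_days, strictly = TRUE)) {
    stop("code_days must be strictly increasing", call. = FALSE)
  }
  data.frame(
    target_code_date = code_days,
    window_start = code_days - as.integer(window_days),
    window_end = code_days + as.integer(window_days),
    stringsAsFactors = FALSE
  )
}

#' Adjudicate one patient's gold-standard HIV status
#'
#' Walks the patient's code days chronologically. The first code day whose
#' chart-review record confirms the diagnosis sets the confirmation date to
#' *that code day*; records for later code days are ignored (the review
#' stop rule — early termination provably never changes the result, since
#' the walk is in date order). A code day with no chart record is treated
#' as reviewed-and-unconfirmed. If no code day confirms, the patient is
#' unconfirmed with evidence `"none"`.
#'
#' Evidence follows the chart hierarchy: a clinician's note stating the
#' diagnosis, or in its absence laboratory evidence (detectable viral load
#' or positive antibody test). Each abstraction record carries the single
#' evidence type that supported it under that hierarchy.
#'
#' @param code_days strictly increasing `Date` vector of the patient's HIV
#'   code days (within follow-up).
#' @param chart_records chart-review records for this patient (see
#'   [read_chart_reviews()]); every `target_code_date` must be a code day,
#'   and a present `evidence_date` must fall inside the review window.
#' @param window_days review-window half-width in days.
#' @return list with `confirmed` (logical), `confirmation_date` (`Date`,
#'   `NA` when unconfirmed) and `evidence`.
#' @export
adjudicate <- function(code_days, chart_records, window_days = 183L) {
  sched <- review_schedule(code_days, window_days)
  stray <- !(chart_records$target_code_date %in% code_days)
  if (any(stray)) {
    stop(sprintf(
      "chart record targets %s which is not a code day for this patient",
      format(chart_records$target_code_date[which(stray)[1]])
    ), call. = FALSE)
  }
  unconfirmed <- list(confirmed = FALSE, confirmation_date = as.Date(NA),
                      evidence = "none")
  if (nrow(sched) == 0) {
    return(unconfirmed)
  }
  for (i in seq_len(nrow(sched))) {
    rec <- chart_records[chart_records$target_code_date ==
                           sched$target_code_date[i], , drop = FALSE]
    if (nrow(rec) == 0 || !any(rec$confirmed)) next
    rec <- rec[rec$confirmed, , drop = FALSE]
    out_of_window <- !is.na(rec$evidence_date) &
      (rec$evidence_date < sched$window_start[i] |
         rec$evidence_date > sched$window_end[i])
    if (any(out_of_window)) {
      stop(sprintf(
        "confirming evidence dated %s lies outside the review window [%s, %s]",
        format(rec$evidence_date[which(out_of_window)[1]]),
        format(sched$window_start[i]), format(sched$window_end[i])
      ), call. = FALSE)
    }
    # clinician note outranks laboratory evidence when both were abstracted
    ev <- if (any(rec$evidence == "clinician_note")) "clinician_note"
    else rec$evidence[1]
    return(list(confirmed = TRUE,
                confirmation_date = sched$target_code_date[i],
                evidence = ev))
  }
  unconfirmed
}

#' Adjudicate every indexed patient
#'
#' Applies [adjudicate()] to each patient with an index event, using the
#' patient's HIV code days inside follow-up and their chart-review records.
#'
#' @param claims claims data frame.
#' @param followups output of [build_followup()].
#' @param index_events output of [find_index_events()]; defines the patient
#'   universe (one confirmation row per indexed patient).
#' @param chart_reviews chart-review records for all patients.
#' @param hiv_set qualifying [code_set].
#' @param window_days review-window half-width in days.
#' @return data frame `patient_id`, `confirmed`, `confirmation_date`,
#'   `evidence`.
#' @export
adjudicate_all <- function(claims, followups, index_events, chart_reviews,
                           hiv_set, window_days = 183L) {
  days_by <- distinct_code_days(claims, hiv_set)
  charts_by <- split(chart_reviews, chart_reviews$patient_id)
  empty_chart <- chart_reviews[0, , drop = FALSE]
  rows <- lapply(seq_len(nrow(index_events)), function(i) {
    pid <- index_events$patient_id[i]
    fu <- followups[match(pid, followups$patient_id), ]
    d <- days_by[[pid]]
    d <- d[d >= fu$entry & d <= fu$exit]
    ch <- charts_by[[pid]]
    if (is.null(ch)) ch <- empty_chart
    # reviews target code days inside follow-up only
    ch <- ch[ch$target_code_date %in% d, , drop = FALSE]
    res <- adjudicate(d, ch, window_days)
    data.frame(patient_id = pid, confirmed = res$confirmed,
               confirmation_date = res$confirmation_date,
               evidence = res$evidence, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(patient_id = character(0), confirmed = logical(0),
                      confirmation_date = as.Date(character(0)),
                      evidence = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Was the diagnosis confirmed on or before a cutoff date?
#'
#' The PPV numerator rule: a patient counts as a true positive for an
#' algorithm when their chart-confirmed diagnosis date falls on or before
#' the date the algorithm's criteria were met (equality counts).
#'
#' @param confirmed logical vector.
#' @param confirmation_date `Date` vector (`NA` when unconfirmed).
#' @param cutoff `Date` vector (recycled).
#' @return logical vector; `FALSE` wherever unconfirmed or the cutoff is `NA`.
#' @export
confirmed_on_or_before <- function(confirmed, confirmation_date, cutoff) {
  out <- confirmed & !is.na(confirmation_date) & !is.na(cutoff) &
    confirmation_date <= cutoff
  out & !is.na(out)
}
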