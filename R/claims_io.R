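# Data model and delimited-file I/O for claims, enrollment, demographics,
# insurance, residency and chart-review abstraction records.
#
# All files are comma-separated UTF-8 with a mandatory header row and
# ISO-8601 dates; all date intervals in the package are closed (both
# endpoints inclusive).

CARE_SETTINGS <- c("inpatient", "outpatient")
EVIDENCE_TYPES <- c("clinician_note", "lab_viral_load", "lab_antibody", "none")

#' @noRd
read_table_file <- function(path, required) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, fileEncoding = "UTF-8")
  check_columns(df, required, path)
  df
}

#' Read administrative claim lines
#'
#' Expects header `patient_id,service_date,system,code,setting`. Codes are
#' normalized on read (dotted and undotted forms are both accepted), dates
#' are validated as ISO-8601, and the `system`/`setting` enumerations are
#' enforced with line-numbered errors. When a `calendar` is supplied, claims
#' whose code system disagrees with their service-date era are flagged with
#' a warning (see [flag_era_mismatches()]) but retained.
#'
#' @param path path to `claims.csv`.
#' @param calendar optional [era_calendar()] used for era/system validation.
#' @param plausible_range length-2 `Date` vector; service dates outside it
#'   are rejected. Defaults to 1990-01-01 through 2099-12-31.
#' @return data frame with columns `patient_id` (character), `service_date`
#'   (`Date`), `system`, `code` (normalized), `setting`.
#' @export
read_claims <- function(path, calendar = NULL,
                        plausible_range = as.Date(c("1990-01-01", "2099-12-31"))) {
  df <- read_table_file(
    path, c("patient_id", "service_date", "system", "code", "setting")
  )
  claims(df$patient_id, df$service_date, df$system, df$code, df$setting,
         calendar = calendar, plausible_range = plausible_range)
}

#' Construct a validated claims data frame
#'
#' @param patient_id,service_date,system,code,setting column vectors.
#' @inheritParams read_claims
#' @return validated claims data frame (see [read_claims()]).
#' @export
claims <- function(patient_id, service_date, system, code, setting,
                   calendar = NULL,
                   plausible_range = as.Date(c("1990-01-01", "2099-12-31"))) {
  df <- data.frame( # data.frame() recycles length-1 columns
    patient_id = as.character(patient_id),
    service_date = as_date_strict(service_date, "service_date"),
    system = system,
    code = as.character(code),
    setting = setting,
    stringsAsFactors = FALSE
  )
  check_enum(df$system, CODE_SYSTEMS, "code system")
  check_enum(df$setting, CARE_SETTINGS, "care setting")
  out_of_range <- !is.na(df$service_date) &
    (df$service_date < plausible_range[1] | df$service_date > plausible_range[2])
  if (any(out_of_range)) {
    i <- which(out_of_range)[1]
    stop(sprintf("implausible service_date %s [row %d]",
                 format(df$service_date[i]), i), call. = FALSE)
  }
  df$code <- vapply(seq_len(nrow(df)),
                    function(i) normalize_code(df$code[i], df$system[i]), "")
  if (!is.null(calendar)) {
    flag_era_mismatches(df, calendar, warn = TRUE)
  }
  df
}

#' Merge overlapping or date-adjacent coverage spans
#'
#' Spans for one patient that overlap, or where one begins the day after the
#' other ends, are merged into a single span. Overlaps trigger a warning
#' (duplicate extraction is worth knowing about); adjacency does not.
#'
#' @param spans data frame with `patient_id`, `start`, `end` (`Date`).
#' @return merged data frame, sorted by patient and start date.
#' @export
#' @examples
#' merge_spans(data.frame(patient_id = "p1",
#'   start = as.Date(c("2010-01-01", "2010-07-01")),
#'   end = as.Date(c("2010-06-30", "2011-01-01"))))  # one span
merge_spans <- function(spans) {
  bad <- spans$start > spans$end
  if (any(bad)) {
    stop(sprintf("span start after end for patient %s [row %d]",
                 spans$patient_id[which(bad)[1]], which(bad)[1]), call. = FALSE)
  }
  spans <- spans[order(spans$patient_id, spans$start, spans$end), , drop = FALSE]
  overlapped <- FALSE
  pieces <- lapply(split(spans, spans$patient_id), function(s) {
    if (nrow(s) == 1L) return(s)
    starts <- s$start[1]
    ends <- s$end[1]
    for (i in 2:nrow(s)) {
      k <- length(ends)
      if (as.integer(s$start[i] - ends[k]) <= 1L) {
        if (s$start[i] <= ends[k]) overlapped <<- TRUE
        ends[k] <- max(ends[k], s$end[i])
      } else {
        starts <- c(starts, s$start[i])
        ends <- c(ends, s$end[i])
      }
    }
    data.frame(patient_id = s$patient_id[1], start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  if (overlapped) {
    warning("overlapping coverage spans were merged", call. = FALSE)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Read enrollment (or residency) coverage spans
#'
#' Expects header `patient_id,start,end`. Per-patient spans are merged when
#' overlapping or date-adjacent.
#'
#' @param path path to the CSV file.
#' @return merged spans data frame (`patient_id`, `start`, `end`).
#' @export
read_enrollment <- function(path) {
  df <- read_table_file(path, c("patient_id", "start", "end"))
  merge_spans(data.frame(
    patient_id = as.character(df$patient_id),
    start = as_date_strict(df$start, "start"),
    end = as_date_strict(df$end, "end"),
    stringsAsFactors = FALSE
  ))
}

#' @rdname read_enrollment
#' @export
read_residency <- read_enrollment

#' Read patient demographics
#'
#' Expects header `patient_id,birth_date,death_date,race_ethnicity`;
#' `death_date` may be blank.
#'
#' @param path path to `demographics.csv`.
#' @return data frame with `Date` columns and character `race_ethnicity`.
#' @export
read_demographics <- function(path) {
  df <- read_table_file(
    path, c("patient_id", "birth_date", "death_date", "race_ethnicity")
  )
  out <- data.frame(
    patient_id = as.character(df$patient_id),
    birth_date = as_date_strict(df$birth_date, "birth_date"),
    death_date = as_date_strict(df$death_date, "death_date"),
    race_ethnicity = as.character(df$race_ethnicity),
    stringsAsFactors = FALSE
  )
  bad <- !is.na(out$death_date) & out$death_date < out$birth_date
  if (any(bad)) {
    stop(sprintf("death_date before birth_date for patient %s",
                 out$patient_id[which(bad)[1]]), call. = FALSE)
  }
  out
}

#' Read insurance history
#'
#' Expects header `patient_id,start,payer`; each row opens a coverage
#' interval that runs until the patient's next `start` date (or indefinitely
#' for the last row).
#'
#' @param path path to `insurance.csv`.
#' @return data frame sorted by patient and start date.
#' @export
read_insurance <- function(path) {
  df <- read_table_file(path, c("patient_id", "start", "payer"))
  check_enum(df$payer, c("Medicaid", "Medicare", "commercial"), "payer")
  out <- data.frame(
    patient_id = as.character(df$patient_id),
    start = as_date_strict(df$start, "start"),
    payer = as.character(df$payer),
    stringsAsFactors = FALSE
  )
  out[order(out$patient_id, out$start), , drop = FALSE]
}

#' Read chart-review abstraction records
#'
#' Expects header `patient_id,target_code_date,confirmed,evidence,evidence_date`.
#' A record abstracts the medical-record review triggered by one diagnosis
#' code day (`target_code_date`). Invariant: `evidence == "none"` exactly
#' when `confirmed` is false, and a confirmed record carries an
#' `evidence_date`.
#'
#' @param path path to `chart_reviews.csv`.
#' @return validated data frame.
#' @export
read_chart_reviews <- function(path) {
  df <- read_table_file(
    path,
    c("patient_id", "target_code_date", "confirmed", "evidence", "evidence_date")
  )
  confirmed <- df$confirmed %in% c("TRUE", "true", "True", "1")
  not_bool <- !(df$confirmed %in%
                  c("TRUE", "true", "True", "1", "FALSE", "false", "False", "0"))
  if (any(not_bool)) {
    stop(sprintf("unparseable confirmed flag '%s' [row %d]",
                 df$confirmed[which(not_bool)[1]], which(not_bool)[1]),
         call. = FALSE)
  }
  check_enum(df$evidence, EVIDENCE_TYPES, "evidence type")
  out <- data.frame(
    patient_id = as.character(df$patient_id),
    target_code_date = as_date_strict(df$target_code_date, "target_code_date"),
    confirmed = confirmed,
    evidence = as.character(df$evidence),
    evidence_date = as_date_strict(df$evidence_date, "evidence_date"),
    stringsAsFactors = FALSE
  )
  bad <- (out$confirmed & out$evidence == "none") |
    (!out$confirmed & out$evidence != "none")
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "chart record for patient %s on %s violates the evidence invariant (confirmed=%s, evidence=%s)",
      out$patient_id[i], format(out$target_code_date[i]),
      out$confirmed[i], out$evidence[i]
    ), call. = FALSE)
  }
  missing_date <- out$confirmed & is.na(out$evidence_date)
  if (any(missing_date)) {
    i <- which(missing_date)[1]
    stop(sprintf("confirmed chart record for patient %s on %s lacks an evidence_date",
                 out$patient_id[i], format(out$target_code_date[i])),
         call. = FALSE)
  }
  out
}

#' Write pipeline data frames as CSV
#'
#' Dates are serialized as ISO-8601 so that a write/read round trip is exact.
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (inherits(out[[nm]], "Date")) out[[nm]] <- format(out[[nm]], "%Y-%m-%d")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Distinct code days per patient
#'
#' Collapses claims matching a code set to the set of distinct calendar days
#' on which at least one matching claim occurred: the unit of every
#' frequency-based phenotyping rule here is "days with a code", never raw
#' claim-line counts. Multiple claims (or multiple qualifying codes) on one
#' day count once.
#'
#' @param claims claims data frame.
#' @param set a [code_set].
#' @param window optional closed date interval (length-2 `Date`) to which
#'   days are restricted, both endpoints inclusive.
#' @return named list, one strictly increasing `Date` vector per patient with
#'   at least one matching day. Patients with none are absent.
#' @export
distinct_code_days <- function(claims, set, window = NULL) {
  keys <- paste(claims$system, claims$code)
  keep <- keys %in% code_set_keys(set)
  if (!is.null(window)) {
    window <- as_date_strict(window, "window")
    stopifnot(length(window) == 2L, window[1] <= window[2])
    keep <- keep & claims$service_date >= window[1] &
      claims$service_date <= window[2]
  }
  matched <- claims[keep, c("patient_id", "service_date")]
  if (nrow(matched) == 0) {
    return(structure(list(), names = character(0)))
  }
  lapply(split(matched$service_date, matched$patient_id),
         function(d) sort(unique(d)))
}
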