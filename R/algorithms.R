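# Declarative rule engine for claims-based classification algorithms:
# "at least k distinct days with a qualifying code", optionally restricted
# to a calendar window, optionally requiring a companion procedure-code day
# on or after the first qualifying code day.

#' Define a claims-based classification algorithm
#'
#' An algorithm is data, not code: a qualifying code set, a minimum number
#' of distinct code days `k`, an optional closed calendar window, an
#' optional cohort restriction on when the patient's *first* HIV code day
#' (under `eligibility_code_set_id`, any HIV code by default) must fall, and
#' an optional companion clause requiring at least one day with a companion
#' code (e.g. a CD4 procedure) on or after the first primary code day.
#'
#' @param id short identifier (e.g. `"1b"`).
#' @param label human-readable rule description.
#' @param code_set_id id of the qualifying code set.
#' @param min_distinct_days minimum number of distinct code days, `k >= 1`.
#' @param window optional length-2 `Date`: code days are counted only inside
#'   this closed interval.
#' @param restrict_first_code_to_window if `TRUE`, only patients whose first
#'   HIV code day during follow-up lies *inside* `window` are eligible
#'   (enter the denominator universe).
#' @param eligibility_code_set_id code set defining "first HIV code day" for
#'   the eligibility restriction; defaults to `"all_hiv"`.
#' @param companion_code_set_id optional companion code set id.
#' @return an object of class `algorithm_spec`.
#' @export
algorithm_spec <- function(id, label, code_set_id,
                           min_distinct_days = 1L,
                           window = NULL,
                           restrict_first_code_to_window = FALSE,
                           eligibility_code_set_id = "all_hiv",
                           companion_code_set_id = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            min_distinct_days >= 1L)
  if (!is.null(window)) {
    window <- as_date_strict(window, "window")
    stopifnot(length(window) == 2L, window[1] <= window[2])
  }
  if (restrict_first_code_to_window && is.null(window)) {
    stop("restrict_first_code_to_window requires a window", call. = FALSE)
  }
  structure(
    list(
      id = id, label = label, code_set_id = code_set_id,
      min_distinct_days = as.integer(min_distinct_days),
      window = window,
      restrict_first_code_to_window = isTRUE(restrict_first_code_to_window),
      eligibility_code_set_id = eligibility_code_set_id,
      companion_code_set_id = companion_code_set_id
    ),
    class = "algorithm_spec"
  )
}

#' @export
print.algorithm_spec <- function(x, ...) {
  cat(sprintf("<algorithm_spec '%s'> %s\n", x$id, x$label))
  cat(sprintf("  >= %d distinct day(s) with codes from '%s'%s\n",
              x$min_distinct_days, x$code_set_id,
              if (!is.null(x$window)) {
                sprintf(" during %s..%s", format(x$window[1]), format(x$window[2]))
              } else ""))
  if (!is.null(x$companion_code_set_id)) {
    cat(sprintf("  plus >= 1 day with codes from '%s' on/after first primary code day\n",
                x$companion_code_set_id))
  }
  invisible(x)
}

#' Is a patient eligible for an algorithm's denominator universe?
#'
#' Calendar-window algorithms restrict the universe to patients whose first
#' HIV code day during follow-up falls inside the window — both bounds
#' inclusive. Without a restriction every indexed patient is eligible.
#' Requiring the first code day to fall *inside* the window (rather than
#' merely on or after its start) makes sub-era universes additive: the
#' early-era and late-era universes partition the era universe.
#'
#' @param spec an [algorithm_spec()].
#' @param first_hiv_code_date the patient's first HIV code day in follow-up.
#' @return logical.
#' @export
eligible <- function(spec, first_hiv_code_date) {
  stopifnot(inherits(spec, "algorithm_spec"))
  if (!spec$restrict_first_code_to_window) {
    return(rep(TRUE, length(first_hiv_code_date)))
  }
  first_hiv_code_date >= spec$window[1] & first_hiv_code_date <= spec$window[2]
}

#' Evaluate one algorithm for one patient
#'
#' Let `D` be the patient's distinct qualifying code days within follow-up,
#' intersected with the spec's window when present. The criteria are met
#' when `|D| >= k` and, when a companion clause exists, at least one
#' companion code day (within follow-up, no window) falls on or after the
#' first primary code day `D[1]`. The criteria-met date is the `k`-th
#' element of `D`, or with a companion clause the later of that day and the
#' earliest qualifying companion day — criteria are not met until both
#' conditions hold.
#'
#' @param spec an [algorithm_spec()].
#' @param primary_days patient's distinct code days for the spec's code set
#'   within follow-up (window not yet applied).
#' @param companion_days patient's distinct companion code days within
#'   follow-up (`NULL` when no companion clause).
#' @return list `met` (logical), `criteria_met_date` (`Date` or `NA`).
#' @export
evaluate_algorithm <- function(spec, primary_days, companion_days = NULL) {
  stopifnot(inherits(spec, "algorithm_spec"))
  d <- primary_days
  if (!is.null(spec$window)) {
    d <- d[d >= spec$window[1] & d <= spec$window[2]]
  }
  not_met <- list(met = FALSE, criteria_met_date = as.Date(NA))
  if (length(d) < spec$min_distinct_days) {
    return(not_met)
  }
  met_date <- d[spec$min_distinct_days]
  if (!is.null(spec$companion_code_set_id)) {
    comp <- companion_days[companion_days >= d[1]]
    if (length(comp) == 0) {
      return(not_met)
    }
    met_date <- max(met_date, comp[1])
  }
  list(met = TRUE, criteria_met_date = met_date)
}

#' Evaluate algorithms across the indexed cohort
#'
#' For each spec, the denominator universe is the eligible indexed patients
#' (see [eligible()]); within it, [evaluate_algorithm()] decides membership
#' and the criteria-met date. Ineligible patients are absent from that
#' algorithm's outcomes (they are outside its universe, not merely
#' non-members).
#'
#' @param specs list of [algorithm_spec()] objects.
#' @param claims claims data frame.
#' @param index_events output of [find_index_events()].
#' @param followups output of [build_followup()].
#' @param codesets named list of [code_set]s resolving every
#'   `code_set_id` referenced by the specs (default [hiv_codesets()]).
#' @return data frame `algorithm_id`, `patient_id`, `in_denominator`,
#'   `criteria_met_date`.
#' @export
evaluate_algorithms <- function(specs, claims, index_events, followups,
                                codesets = hiv_codesets()) {
  if (inherits(specs, "algorithm_spec")) specs <- list(specs)
  fu <- followups[match(index_events$patient_id, followups$patient_id), ]

  set_ids <- unique(unlist(lapply(specs, function(s) {
    c(s$code_set_id, s$companion_code_set_id)
  })))
  missing <- setdiff(set_ids, names(codesets))
  if (length(missing)) {
    stop(sprintf("unknown code set id(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  # per-set, per-patient code days clipped to follow-up, computed once
  days_in_fu <- lapply(codesets[set_ids], function(set) {
    by <- distinct_code_days(claims, set)
    lapply(seq_len(nrow(index_events)), function(i) {
      d <- by[[index_events$patient_id[i]]]
      d[d >= fu$entry[i] & d <= fu$exit[i]]
    })
  })

  out <- lapply(specs, function(spec) {
    elig <- eligible(spec, index_events$first_hiv_code_date)
    idx <- which(elig)
    if (length(idx) == 0) {
      return(data.frame(
        algorithm_id = character(0), patient_id = character(0),
        in_denominator = logical(0),
        criteria_met_date = as.Date(character(0)), stringsAsFactors = FALSE
      ))
    }
    res <- lapply(idx, function(i) {
      evaluate_algorithm(
        spec,
        primary_days = days_in_fu[[spec$code_set_id]][[i]],
        companion_days = if (!is.null(spec$companion_code_set_id)) {
          days_in_fu[[spec$companion_code_set_id]][[i]]
        }
      )
    })
    data.frame(
      algorithm_id = spec$id,
      patient_id = index_events$patient_id[idx],
      in_denominator = vapply(res, `[[`, TRUE, "met"),
      criteria_met_date = as.Date(
        vapply(res, function(r) as.numeric(r$criteria_met_date), 0),
        origin = "1970-01-01"
      ),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' The built-in validation algorithm suite
#'
#' The eighteen algorithms evaluated in the validation table, in table
#' order:
#'
#' * `1a`–`1c`: at least 1, 2, 3 distinct days with any HIV diagnosis code,
#'   no calendar restriction;
#' * `2a`–`2c`: at least 1 HIV code day during the ICD-9-CM era
#'   (2010-01-01–2015-09-30) and its earlier (2010–2012) / later
#'   (2013–2015-09-30) halves, each restricted to patients whose first HIV
#'   code day falls inside the window;
#' * `3a`–`3c`: the same for the ICD-10-CM era (2015-10-01–2020-12-31) and
#'   its earlier (2015-10-01–2017) / later (2018–2020) halves;
#' * `4a`–`4d`: at least 1 day with the individual ICD-9-CM code 042, V08,
#'   079.53 or 795.71, among patients whose first HIV code day (any HIV
#'   code) falls in the ICD-9-CM era;
#' * `5a`–`5d`: at least 1 day with the individual ICD-10-CM code B20, Z21,
#'   B97.35 or the O98.711–O98.73 group, among patients whose first HIV
#'   code day falls in the ICD-10-CM era;
#' * `6a`: at least 1 HIV code day plus at least 1 CD4 procedure-code day
#'   (CPT 86360/86361) on or after the first HIV code day.
#'
#' For the individual-code rows the eligibility clock runs on *any* HIV
#' code while the day count requires the *specific* code — so one patient
#' can appear in several rows of the same era, and the era rows' universes
#' partition the overall universe.
#'
#' @param calendar an [era_calendar()] supplying the era boundaries.
#' @return named list of [algorithm_spec()] objects in table order.
#' @export
builtin_algorithm_specs <- function(calendar = era_calendar()) {
  icd9 <- c(calendar$icd9_start, calendar$icd9_end)
  icd10 <- c(calendar$icd10_start, calendar$study_end)
  icd9_split <- as.Date(c("2012-12-31", "2013-01-01"))
  icd10_split <- as.Date(c("2017-12-31", "2018-01-01"))
  win <- function(a, b) c(a, b)
  specs <- list(
    algorithm_spec("1a", ">= 1 day with an HIV diagnosis code", "all_hiv", 1L),
    algorithm_spec("1b", ">= 2 days with an HIV diagnosis code", "all_hiv", 2L),
    algorithm_spec("1c", ">= 3 days with an HIV diagnosis code", "all_hiv", 3L),
    algorithm_spec("2a", ">= 1 HIV code day, ICD-9-CM era", "all_hiv", 1L,
                   window = icd9, restrict_first_code_to_window = TRUE),
    algorithm_spec("2b", ">= 1 HIV code day, earlier ICD-9-CM era", "all_hiv", 1L,
                   window = win(icd9[1], icd9_split[1]),
                   restrict_first_code_to_window = TRUE),
    algorithm_spec("2c", ">= 1 HIV code day, later ICD-9-CM era", "all_hiv", 1L,
                   window = win(icd9_split[2], icd9[2]),
                   restrict_first_code_to_window = TRUE),
    algorithm_spec("3a", ">= 1 HIV code day, ICD-10-CM era", "all_hiv", 1L,
                   window = icd10, restrict_first_code_to_window = TRUE),
    algorithm_spec("3b", ">= 1 HIV code day, earlier ICD-10-CM era", "all_hiv", 1L,
                   window = win(icd10[1], icd10_split[1]),
                   restrict_first_code_to_window = TRUE),
    algorithm_spec("3c", ">= 1 HIV code day, later ICD-10-CM era", "all_hiv", 1L,
                   window = win(icd10_split[2], icd10[2]),
                   restrict_first_code_to_window = TRUE),
    algorithm_spec("4a", ">= 1 day with ICD-9-CM 042", "icd9_042", 1L,
                   window = icd9, restrict_first_code_to_window = TRUE),
    algorithm_spec("4b", ">= 1 day with ICD-9-CM V08", "icd9_V08", 1L,
                   window = icd9, restrict_first_code_to_window = TRUE),
    algorithm_spec("4c", ">= 1 day with ICD-9-CM 079.53", "icd9_07953", 1L,
                   window = icd9, restrict_first_code_to_window = TRUE),
    algorithm_spec("4d", ">= 1 day with ICD-9-CM 795.71", "icd9_79571", 1L,
                   window = icd9, restrict_first_code_to_window = TRUE),
    algorithm_spec("5a", ">= 1 day with ICD-10-CM B20", "icd10_B20", 1L,
                   window = icd10, restrict_first_code_to_window = TRUE),
    algorithm_spec("5b", ">= 1 day with ICD-10-CM Z21", "icd10_Z21", 1L,
                   window = icd10, restrict_first_code_to_window = TRUE),
    algorithm_spec("5c", ">= 1 day with ICD-10-CM B97.35", "icd10_B9735", 1L,
                   window = icd10, restrict_first_code_to_window = TRUE),
    algorithm_spec("5d", ">= 1 day with ICD-10-CM O98.711-O98.73",
                   "icd10_pregnancy", 1L,
                   window = icd10, restrict_first_code_to_window = TRUE),
    algorithm_spec("6a", ">= 1 HIV code day & >= 1 CD4 procedure day on/after first HIV code",
                   "all_hiv", 1L, companion_code_set_id = "cd4_cpt")
  )
  names(specs) <- vapply(specs, `[[`, "", "id")
  specs
}

#' Read / write algorithm specs as a YAML config
#'
#' One block per spec mirroring the [algorithm_spec()] fields, so new
#' algorithms can be defined without touching the engine.
#'
#' @param specs named list of [algorithm_spec()]s.
#' @param path file path.
#' @return `read_algorithm_config()` returns a named list of specs;
#'   `write_algorithm_config()` returns `path` invisibly.
#' @export
write_algorithm_config <- function(specs, path) {
  blocks <- lapply(specs, function(s) {
    b <- list(
      id = s$id, label = s$label, code_set_id = s$code_set_id,
      min_distinct_days = s$min_distinct_days,
      restrict_first_code_to_window = s$restrict_first_code_to_window,
      eligibility_code_set_id = s$eligibility_code_set_id
    )
    if (!is.null(s$window)) {
      b$window <- list(start = format(s$window[1]), end = format(s$window[2]))
    }
    if (!is.null(s$companion_code_set_id)) {
      b$companion_code_set_id <- s$companion_code_set_id
    }
    b
  })
  yaml::write_yaml(unname(blocks), path)
  invisible(path)
}

#' @rdname write_algorithm_config
#' @export
read_algorithm_config <- function(path) {
  blocks <- yaml::read_yaml(path)
  specs <- lapply(blocks, function(b) {
    algorithm_spec(
      id = b$id, label = b$label %||% b$id, code_set_id = b$code_set_id,
      min_distinct_days = b$min_distinct_days %||% 1L,
      window = if (!is.null(b$window)) {
        as.Date(c(b$window$start, b$window$end))
      },
      restrict_first_code_to_window = isTRUE(b$restrict_first_code_to_window),
      eligibility_code_set_id = b$eligibility_code_set_id %||% "all_hiv",
      companion_code_set_id = b$companion_code_set_id
    )
  })
  names(specs) <- vapply(specs, `[[`, "", "id")
  specs
}
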