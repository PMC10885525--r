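# Diagnosis/procedure code sets, code normalization, and the ICD-9/ICD-10
# era calendar used to classify service dates.

CODE_SYSTEMS <- c("ICD9CM-DX", "ICD10CM-DX", "CPT")

#' Normalize a diagnosis or procedure code
#'
#' Canonical form: uppercase, dot characters removed, surrounding whitespace
#' stripped. Codes are always strings — ICD-9-CM leading zeros (e.g. `"042"`)
#' are significant and preserved. The transformation is idempotent.
#'
#' @param raw character vector of raw codes (dotted or undotted).
#' @param system code system the codes belong to, one of
#'   `"ICD9CM-DX"`, `"ICD10CM-DX"`, `"CPT"`. Currently informational
#'   (normalization is system-independent) but validated.
#' @return character vector of normalized codes.
#' @export
#' @examples
#' normalize_code("O98.711", "ICD10CM-DX")  # "O98711"
#' normalize_code("042", "ICD9CM-DX")       # "042" — leading zero retained
normalize_code <- function(raw, system = "ICD10CM-DX") {
  check_enum(system, CODE_SYSTEMS, "code system")
  if (length(raw) == 0) {
    return(character(0))
  }
  raw <- as.character(raw)
  out <- toupper(gsub(".", "", trimws(raw), fixed = TRUE))
  bad <- is.na(out) | !nzchar(out)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "empty or whitespace-only code at position %d (raw value: %s)",
      i, deparse(raw[i])
    ), call. = FALSE)
  }
  out
}

#' Construct a code set
#'
#' A code set is a named collection of normalized codes, each tagged with its
#' code system. Single-system sets are the building blocks; [code_set_union()]
#' combines them across systems (e.g. an all-era HIV set).
#'
#' @param id short identifier (e.g. `"icd9_hiv"`).
#' @param system code system for all codes in the set.
#' @param codes character vector of codes (normalized on input).
#' @param label human-readable description.
#' @return an object of class `code_set` with an `elements` data frame
#'   (`system`, `code`).
#' @export
code_set <- function(id, system, codes, label = id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  check_enum(system, CODE_SYSTEMS, "code system")
  codes <- unique(normalize_code(codes, system))
  if (length(codes) == 0) {
    stop("a code set must contain at least one code", call. = FALSE)
  }
  structure(
    list(
      id = id,
      label = label,
      elements = data.frame(
        system = rep(system, length(codes)),
        code = codes,
        stringsAsFactors = FALSE
      )
    ),
    class = "code_set"
  )
}

#' Union of code sets
#'
#' @param id identifier for the combined set.
#' @param sets list of `code_set` objects.
#' @param label human-readable description.
#' @return a `code_set` whose elements are the union of the inputs. A code
#'   string may not appear under two different systems within the result.
#' @export
code_set_union <- function(id, sets, label = id) {
  stopifnot(length(sets) >= 1, all(vapply(sets, inherits, TRUE, "code_set")))
  el <- unique(do.call(rbind, lapply(sets, `[[`, "elements")))
  dup <- duplicated(el$code) | duplicated(el$code, fromLast = TRUE)
  if (any(dup)) {
    stop(sprintf(
      "code(s) %s appear under more than one system in set '%s'",
      paste(unique(el$code[dup]), collapse = ", "), id
    ), call. = FALSE)
  }
  rownames(el) <- NULL
  structure(list(id = id, label = label, elements = el), class = "code_set")
}

#' @export
print.code_set <- function(x, ...) {
  cat(sprintf(
    "<code_set '%s'> %s\n  %d code(s): %s\n",
    x$id, x$label, nrow(x$elements),
    paste(paste0(x$elements$system, ":", x$elements$code), collapse = " ")
  ))
  invisible(x)
}

#' @noRd
code_set_keys <- function(set) {
  stopifnot(inherits(set, "code_set"))
  paste(set$elements$system, set$elements$code)
}

#' Built-in HIV diagnosis and CD4 procedure code sets
#'
#' The HIV vocabulary across the U.S. ICD-9-CM/ICD-10-CM transition:
#'
#' * `icd9_hiv`: 042 (HIV disease), V08 (asymptomatic HIV), 079.53
#'   (HIV type 2), 795.71 (nonspecific serologic evidence of HIV);
#' * `icd10_hiv`: B20, Z21, B97.35, and the pregnancy/childbirth/puerperium
#'   group O98.711–O98.73;
#' * `icd10_pregnancy`: the six valid codes in the O98.711–O98.73 range
#'   (O98.711, O98.712, O98.713, O98.719, O98.72, O98.73) — a range
#'   enumeration, not a prefix match, so unlisted O98.7x subcodes never
#'   qualify;
#' * one singleton set per individual diagnosis code
#'   (`icd9_042`, ..., `icd10_B9735`);
#' * `cd4_cpt`: CPT 86360 and 86361 (CD4 T-cell count procedures);
#' * `all_hiv`: the union of the two era vocabularies (disjoint by
#'   construction; CD4 procedure codes are *not* included).
#'
#' @return named list of [code_set] objects, keyed by set id.
#' @export
#' @examples
#' sets <- hiv_codesets()
#' sets$cd4_cpt$elements$code      # "86360" "86361"
#' nrow(sets$icd10_pregnancy$elements)  # 6
hiv_codesets <- function() {
  o98 <- c("O98.711", "O98.712", "O98.713", "O98.719", "O98.72", "O98.73")
  sets <- list(
    code_set("icd9_hiv", "ICD9CM-DX", c("042", "V08", "079.53", "795.71"),
             "ICD-9-CM HIV diagnosis codes"),
    code_set("icd10_hiv", "ICD10CM-DX", c("B20", "Z21", "B97.35", o98),
             "ICD-10-CM HIV diagnosis codes"),
    code_set("icd9_042", "ICD9CM-DX", "042", "ICD-9-CM 042 (HIV disease)"),
    code_set("icd9_V08", "ICD9CM-DX", "V08",
             "ICD-9-CM V08 (asymptomatic HIV infection status)"),
    code_set("icd9_07953", "ICD9CM-DX", "079.53", "ICD-9-CM 079.53 (HIV-2)"),
    code_set("icd9_79571", "ICD9CM-DX", "795.71",
             "ICD-9-CM 795.71 (nonspecific serologic evidence of HIV)"),
    code_set("icd10_B20", "ICD10CM-DX", "B20", "ICD-10-CM B20 (HIV disease)"),
    code_set("icd10_Z21", "ICD10CM-DX", "Z21",
             "ICD-10-CM Z21 (asymptomatic HIV infection status)"),
    code_set("icd10_B9735", "ICD10CM-DX", "B97.35", "ICD-10-CM B97.35 (HIV-2)"),
    code_set("icd10_pregnancy", "ICD10CM-DX", o98,
             "ICD-10-CM O98.711-O98.73 (HIV in pregnancy/childbirth/puerperium)"),
    code_set("cd4_cpt", "CPT", c("86360", "86361"),
             "CPT CD4 T-cell count procedures")
  )
  names(sets) <- vapply(sets, `[[`, "", "id")
  sets$all_hiv <- code_set_union(
    "all_hiv", list(sets$icd9_hiv, sets$icd10_hiv),
    "HIV diagnosis codes, either era vocabulary"
  )
  sets
}

#' ICD coding-era calendar
#'
#' Defines the study period and the calendar date on which the institution
#' switched diagnosis vocabularies. The ICD-9-CM era runs from `icd9_start`
#' through `icd9_end`; the ICD-10-CM era begins the next calendar day
#' (`icd10_start`) and runs through `study_end`. Defaults reflect the U.S.
#' transition of 2015-10-01 within a 2010–2020 study window.
#'
#' @param icd9_start,icd9_end,icd10_start,study_end `Date` (or ISO strings).
#' @return an object of class `era_calendar`.
#' @export
era_calendar <- function(icd9_start = as.Date("2010-01-01"),
                         icd9_end = as.Date("2015-09-30"),
                         icd10_start = as.Date("2015-10-01"),
                         study_end = as.Date("2020-12-31")) {
  cal <- list(
    icd9_start = as_date_strict(icd9_start, "icd9_start"),
    icd9_end = as_date_strict(icd9_end, "icd9_end"),
    icd10_start = as_date_strict(icd10_start, "icd10_start"),
    study_end = as_date_strict(study_end, "study_end")
  )
  if (!(cal$icd9_start <= cal$icd9_end)) {
    stop("icd9_start must not be after icd9_end", call. = FALSE)
  }
  if (as.integer(cal$icd10_start - cal$icd9_end) != 1L) {
    stop("icd10_start must be the calendar day after icd9_end", call. = FALSE)
  }
  if (!(cal$icd10_start <= cal$study_end)) {
    stop("icd10_start must not be after study_end", call. = FALSE)
  }
  structure(cal, class = "era_calendar")
}

#' Coding era of a service date
#'
#' @param service_date `Date` vector.
#' @param calendar an [era_calendar()].
#' @return character vector, `"ICD9_ERA"` or `"ICD10_ERA"`. The boundary day
#'   (`icd10_start`) belongs to the ICD-10 era.
#' @export
#' @examples
#' era_of(as.Date(c("2015-09-30", "2015-10-01")))  # "ICD9_ERA" "ICD10_ERA"
era_of <- function(service_date, calendar = era_calendar()) {
  stopifnot(inherits(calendar, "era_calendar"))
  service_date <- as_date_strict(service_date, "service_date")
  out_of_range <- !is.na(service_date) &
    (service_date < calendar$icd9_start | service_date > calendar$study_end)
  if (any(out_of_range)) {
    stop(sprintf(
      "service date %s outside the study period [%s, %s]",
      format(service_date[which(out_of_range)[1]]),
      format(calendar$icd9_start), format(calendar$study_end)
    ), call. = FALSE)
  }
  ifelse(service_date <= calendar$icd9_end, "ICD9_ERA", "ICD10_ERA")
}

#' Flag claims whose code system disagrees with their service-date era
#'
#' An ICD-9-CM claim dated in the ICD-10 era (or vice versa) usually signals
#' an extraction problem. Mismatches are reported, not dropped: CPT procedure
#' codes are era-independent and never flagged.
#'
#' @param claims a claims data frame (see [read_claims()]).
#' @param calendar an [era_calendar()].
#' @param warn emit a warning when mismatches are found (default `TRUE`).
#' @return the offending rows of `claims` (zero rows when clean), invisibly
#'   when empty.
#' @export
flag_era_mismatches <- function(claims, calendar = era_calendar(), warn = TRUE) {
  era <- era_of(claims$service_date, calendar)
  bad <- (claims$system == "ICD9CM-DX" & era == "ICD10_ERA") |
    (claims$system == "ICD10CM-DX" & era == "ICD9_ERA")
  out <- claims[bad, , drop = FALSE]
  if (nrow(out) && warn) {
    warning(sprintf(
      "%d claim(s) have a code system inconsistent with their service-date era",
      nrow(out)
    ), call. = FALSE)
  }
  if (nrow(out)) out else invisible(out)
}

#' Write / read code-set definitions as a YAML config
#'
#' One section per set (`id`, `system`(s), `codes`, `label`) so other
#' conditions' vocabularies can be swapped in without touching code.
#'
#' @param sets named list of [code_set] objects.
#' @param path file path.
#' @return `read_codeset_config()` returns a named list of `code_set`s;
#'   `write_codeset_config()` returns `path` invisibly.
#' @export
write_codeset_config <- function(sets, path) {
  blocks <- lapply(sets, function(s) {
    list(
      id = s$id, label = s$label,
      codes = lapply(seq_len(nrow(s$elements)), function(i) {
        list(system = s$elements$system[i], code = s$elements$code[i])
      })
    )
  })
  yaml::write_yaml(unname(blocks), path)
  invisible(path)
}

#' @rdname write_codeset_config
#' @export
read_codeset_config <- function(path) {
  blocks <- yaml::read_yaml(path)
  sets <- lapply(blocks, function(b) {
    stopifnot(!is.null(b$id), length(b$codes) >= 1)
    el <- do.call(rbind, lapply(b$codes, function(cc) {
      check_enum(cc$system, CODE_SYSTEMS, "code system")
      data.frame(system = cc$system,
                 code = normalize_code(cc$code, cc$system),
                 stringsAsFactors = FALSE)
    }))
    per_system <- split(el$code, el$system)
    singles <- lapply(names(per_system), function(sys) {
      code_set(b$id, sys, per_system[[sys]], b$label %||% b$id)
    })
    if (length(singles) == 1L) singles[[1]]
    else code_set_union(b$id, singles, b$label %||% b$id)
  })
  names(sets) <- vapply(sets, `[[`, "", "id")
  sets
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
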