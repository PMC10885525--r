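#' Round half-up to a fixed number of decimals
#'
#' Base `round()` uses round-half-to-even; published clinical tables are
#' conventionally rounded half-up (0.05 rounds to 0.1), so percentages are
#' rounded with this helper throughout.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return `x` rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(93.95)  # 94.0, where round(93.95, 1) gives 93.9
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' @noRd
as_date_strict <- function(x, what = "date") {
  if (inherits(x, "Date")) {
    return(x)
  }
  x <- as.character(x)
  out <- as.Date(rep(NA_character_, length(x)))
  nonblank <- !is.na(x) & nzchar(trimws(x))
  parsed <- as.Date(x[nonblank], format = "%Y-%m-%d")
  if (anyNA(parsed)) {
    bad <- which(nonblank)[is.na(parsed)]
    stop(sprintf(
      "unparseable %s (expected ISO-8601 YYYY-MM-DD): %s [row %s]",
      what, x[bad[1]], bad[1]
    ), call. = FALSE)
  }
  out[nonblank] <- parsed
  out
}

#' @noRd
check_enum <- function(x, allowed, what, allow_na = FALSE) {
  bad <- !(x %in% allowed)
  if (allow_na) bad <- bad & !is.na(x)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "unknown %s '%s' [row %s]; expected one of: %s",
      what, x[i], i, paste(allowed, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(x)
}

#' @noRd
check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf(
      "file '%s' is missing required column(s): %s",
      path, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(df)
}

#' Age in completed years at a reference date
#'
#' Calendar-correct integer age: the birthday-anniversary rule, not a
#' days/365.25 approximation.
#'
#' @param birth_date,at `Date` vectors (recycled).
#' @return integer vector of completed years.
#' @export
age_at <- function(birth_date, at) {
  birth_date <- as_date_strict(birth_date, "birth_date")
  at <- as_date_strict(at, "reference date")
  b <- as.POSIXlt(birth_date)
  a <- as.POSIXlt(at)
  age <- a$year - b$year
  not_yet <- (a$mon < b$mon) | (a$mon == b$mon & a$mday < b$mday)
  as.integer(age - not_yet)
}

#' @noRd
add_years <- function(date, years) {
  lt <- as.POSIXlt(date)
  lt$year <- lt$year + years
  out <- as.Date(lt)
  # Feb 29 anniversaries in a non-leap year roll over to Mar 1; pull back
  # to Feb 28 so the anniversary never lands after the calendar date.
  feb29 <- !is.na(date) & format(date, "%m-%d") == "02-29" &
    format(out, "%m-%d") == "03-01"
  out[feb29] <- out[feb29] - 1
  out
}
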