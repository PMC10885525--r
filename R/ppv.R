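# Positive predictive values with Wilson score confidence intervals, and
# assembly of validation-table cells from algorithm outcomes and
# gold-standard confirmations.

#' Wilson score confidence interval for a binomial proportion
#'
#' Inverts the normal-approximate score test: with `p-hat = n/N` and `z` the
#' standard-normal quantile at `(1 + level)/2`,
#' \deqn{center = (\hat p + z^2/2N) / (1 + z^2/N)}
#' \deqn{halfwidth = z \sqrt{\hat p (1-\hat p)/N + z^2/4N^2} / (1 + z^2/N)}
#' and the interval is `center +/- halfwidth`, clipped to `[0, 1]`. Unlike
#' the Wald interval it behaves sensibly at small `N` and at proportions
#' near 0 or 1 (at `n = N` the upper bound is exactly 1). `z` is the exact
#' quantile (1.959964... at the default level), not 1.96.
#'
#' @param n number of successes (vectorized).
#' @param N number of trials, `N >= 1`.
#' @param conf_level confidence level in (0, 1); default 0.95.
#' @return data frame with columns `low`, `high` (proportions).
#' @export
#' @examples
#' wilson_interval(219, 272)  # 0.754, 0.848 at 3 decimals
wilson_interval <- function(n, N, conf_level = 0.95) {
  stopifnot(length(conf_level) == 1L, conf_level > 0, conf_level < 1)
  if (any(N < 1)) stop("N must be at least 1", call. = FALSE)
  if (any(n < 0 | n > N)) stop("n must satisfy 0 <= n <= N", call. = FALSE)
  z <- stats::qnorm((1 + conf_level) / 2)
  p <- n / N
  denom <- 1 + z^2 / N
  center <- (p + z^2 / (2 * N)) / denom
  halfwidth <- z * sqrt(p * (1 - p) / N + z^2 / (4 * N^2)) / denom
  data.frame(low = pmax(0, center - halfwidth),
             high = pmin(1, center + halfwidth))
}

#' Positive predictive value as a percentage
#'
#' `100 * n / N`, rounded half-up to one decimal — the convention of
#' published validation tables.
#'
#' @param n confirmed positives.
#' @param N patients meeting the algorithm criteria, `N >= 1`.
#' @return percentage rounded to 1 decimal.
#' @export
#' @examples
#' ppv(216, 230)  # 93.9
ppv <- function(n, N) {
  if (any(N < 1)) stop("N must be at least 1", call. = FALSE)
  if (any(n < 0 | n > N)) stop("n must satisfy 0 <= n <= N", call. = FALSE)
  round_half_up(100 * n / N, 1)
}

#' Build one validation cell from counts
#'
#' @param algorithm_id identifier.
#' @param N denominator (patients meeting criteria).
#' @param n numerator (confirmed on or before the criteria-met date).
#' @param conf_level confidence level for the Wilson interval.
#' @param label optional rule description.
#' @return one-row data frame `algorithm_id`, `label`, `N`, `n`,
#'   `ppv_pct`, `ci_low_pct`, `ci_high_pct`, `estimable`. When `N == 0` the
#'   cell is flagged not estimable and the percentage columns are `NA`.
#' @export
validation_cell <- function(algorithm_id, N, n, conf_level = 0.95,
                            label = NA_character_) {
  if (N == 0) {
    if (n != 0) stop("n must be 0 when N is 0", call. = FALSE)
    return(data.frame(
      algorithm_id = algorithm_id, label = label, N = 0L, n = 0L,
      ppv_pct = NA_real_, ci_low_pct = NA_real_, ci_high_pct = NA_real_,
      estimable = FALSE, stringsAsFactors = FALSE
    ))
  }
  ci <- wilson_interval(n, N, conf_level)
  data.frame(
    algorithm_id = algorithm_id, label = label,
    N = as.integer(N), n = as.integer(n),
    ppv_pct = ppv(n, N),
    ci_low_pct = round_half_up(100 * ci$low, 1),
    ci_high_pct = round_half_up(100 * ci$high, 1),
    estimable = TRUE, stringsAsFactors = FALSE
  )
}

#' Assemble the validation table from outcomes and confirmations
#'
#' For each algorithm: `N` counts the patients in its universe meeting the
#' criteria; `n` counts those among them whose gold-standard confirmation
#' date falls on or before their criteria-met date.
#'
#' @param outcomes output of [evaluate_algorithms()].
#' @param confirmations output of [adjudicate_all()].
#' @param specs optional named list of [algorithm_spec()]s supplying labels
#'   and row order.
#' @param conf_level confidence level.
#' @return data frame of validation cells, one row per algorithm.
#' @export
validation_table <- function(outcomes, confirmations, specs = NULL,
                             conf_level = 0.95) {
  stray <- setdiff(outcomes$patient_id, confirmations$patient_id)
  if (length(stray)) {
    stop(sprintf("no confirmation record for patient(s): %s",
                 paste(utils::head(stray, 5), collapse = ", ")), call. = FALSE)
  }
  m <- match(outcomes$patient_id, confirmations$patient_id)
  hit <- outcomes$in_denominator & confirmed_on_or_before(
    confirmations$confirmed[m], confirmations$confirmation_date[m],
    outcomes$criteria_met_date
  )
  ids <- if (!is.null(specs)) {
    vapply(specs, `[[`, "", "id")
  } else {
    unique(outcomes$algorithm_id)
  }
  rows <- lapply(ids, function(id) {
    sel <- outcomes$algorithm_id == id
    validation_cell(
      id,
      N = sum(outcomes$in_denominator[sel]),
      n = sum(hit[sel]),
      conf_level = conf_level,
      label = if (!is.null(specs)) specs[[id]]$label else NA_character_
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a validation table as markdown lines
#'
#' Percentages are shown to exactly one decimal; non-estimable cells render
#' as `N/A`.
#'
#' @param cells output of [validation_table()] or [evaluate_counts()].
#' @return character vector of markdown lines.
#' @export
render_validation_table <- function(cells) {
  fmt <- function(x) ifelse(is.na(x), "N/A", sprintf("%.1f", x))
  body <- vapply(seq_len(nrow(cells)), function(i) {
    with(cells[i, ], sprintf(
      "| %s | %s | %d | %d | %s | %s |",
      algorithm_id, ifelse(is.na(label), "", label), N, n, fmt(ppv_pct),
      if (estimable) sprintf("(%s-%s)", fmt(ci_low_pct), fmt(ci_high_pct))
      else "N/A"
    ))
  }, "")
  c("| Algorithm | Description | N | n | PPV (%) | 95% CI |",
    "|---|---|---|---|---|---|",
    body)
}
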