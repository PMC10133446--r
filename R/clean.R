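#' Exclude participants with excessive error rates
#'
#' Participants whose error rate on target sequences is at or above
#' `max_error` are dropped (the criterion keeps error rates strictly
#' below the threshold; 40% exactly is excluded). Missing responses
#' count as errors.
#'
#' @param records A trial-record table with `participant` and `correct`
#'   columns.
#' @param max_error Exclusion threshold on the error rate (default 0.40).
#' @return A list: `records` (surviving rows), `excluded` (tibble of
#'   dropped participants and their error rates), `error_rates` (all
#'   participants).
#' @export
exclude_participants <- function(records, max_error = 0.40) {
  rates <- records |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(error_rate = mean(!.data$correct), .groups = "drop")
  excluded <- dplyr::filter(rates, .data$error_rate >= max_error)
  list(
    records = dplyr::filter(records,
                            !.data$participant %in% excluded$participant),
    excluded = excluded,
    error_rates = rates
  )
}

#' Trim trial records the way the reaction-time analysis requires
#'
#' Removes, in order: trials without a response before the deadline;
#' trials with reaction times under `floor_ms`; and, per participant
#' by singleton condition, trials whose reaction time lies more than
#' `k_sd` standard deviations from that cell's mean (one pass, sample
#' SD over the cell's remaining trials). Cells with fewer than 3
#' trials are passed through untrimmed with a warning, since a
#' two-point SD is meaningless.
#'
#' @param records A trial-record table with `participant`, `condition`,
#'   `response`, `correct` and `rt_ms` columns.
#' @param floor_ms Anticipation floor in ms (default 100).
#' @param k_sd SD multiple for the trimming band (default 2).
#' @return A list: `records` (kept rows) and `report`, a
#'   `cleaning_report` with the kept fractions (all trials, and
#'   correct trials as a fraction of all) and per-rule removal counts.
#' @export
#' @examples
#' plan <- generate_plan(experiment_config("exp1"), seed = 1)
#' recs <- simulate_cohort(plan, 3, observer_population(), seed = 1)
#' cleaned <- clean_trials(recs)
#' cleaned$report
clean_trials <- function(records, floor_ms = 100, k_sd = 2) {
  n_total <- nrow(records)
  no_answer <- records$response == "none" | is.na(records$rt_ms)
  kept <- records[!no_answer, ]
  too_fast <- kept$rt_ms < floor_ms
  kept <- kept[!too_fast, ]

  kept <- kept |>
    dplyr::group_by(.data$participant, .data$condition) |>
    dplyr::mutate(
      .cell_n = dplyr::n(),
      .outlier = .data$.cell_n >= 3 &
        abs(.data$rt_ms - mean(.data$rt_ms)) > k_sd * sd(.data$rt_ms)
    ) |>
    dplyr::ungroup()
  small_cells <- kept |>
    dplyr::filter(.data$.cell_n < 3) |>
    dplyr::distinct(.data$participant, .data$condition)
  if (nrow(small_cells) > 0) {
    warning(nrow(small_cells),
            " participant-by-condition cell(s) had fewer than 3 trials",
            " and were not trimmed")
  }
  n_sd <- sum(kept$.outlier)
  kept <- kept[!kept$.outlier, !names(kept) %in% c(".cell_n", ".outlier")]

  report <- structure(
    list(
      n_total = n_total,
      kept_fraction_all = nrow(kept) / n_total,
      kept_fraction_correct = sum(kept$correct) / n_total,
      removed_by_rule = c(no_answer = sum(no_answer),
                          floor = sum(too_fast), sd = n_sd)
    ),
    class = "cleaning_report"
  )
  list(records = kept, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf(
    "<cleaning_report> %.1f%% of %d trials kept (%.1f%% kept and correct)\n",
    100 * x$kept_fraction_all, x$n_total, 100 * x$kept_fraction_correct
  ))
  cat(sprintf("  removed: %d no-answer, %d under floor, %d beyond the SD band\n",
              x$removed_by_rule["no_answer"], x$removed_by_rule["floor"],
              x$removed_by_rule["sd"]))
  invisible(x)
}
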