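#' Per-participant, per-condition summaries
#'
#' Mean and SD of correct reaction times, error rate over answered
#' trials, LISAS, and trial counts, for every participant by singleton
#' condition cell of a (normally cleaned) trial-record table.
#'
#' @param records Trial records with `participant`, `condition`,
#'   `correct` and `rt_ms` columns.
#' @return A tibble, one row per participant-by-condition cell.
#' @export
summarize_conditions <- function(records) {
  records |>
    dplyr::group_by(.data$participant, .data$condition) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_correct = sum(.data$correct),
      mean_rt_correct = mean(.data$rt_ms[.data$correct]),
      sd_rt = sd(.data$rt_ms[.data$correct]),
      error_rate = mean(!.data$correct),
      lisas = lisas(.data$rt_ms, .data$correct),
      .groups = "drop"
    )
}

#' Per-participant reaction-time increases over the no-singleton baseline
#'
#' For every participant, the mean correct reaction time of each
#' singleton condition minus the same participant's no-singleton mean.
#'
#' @param summaries Output of [summarize_conditions()].
#' @param records The records the summaries came from (used to recover
#'   each condition's jnd deviations).
#' @return A tibble: participant, condition, jnd columns, baseline and
#'   `increase_ms`.
#' @export
rt_increases <- function(summaries, records) {
  jnds <- records |>
    dplyr::distinct(.data$condition, .data$sc_jnd, .data$depth_jnd,
                    .data$jnd_total)
  baseline <- summaries |>
    dplyr::filter(.data$condition == "none") |>
    dplyr::select("participant", baseline_ms = "mean_rt_correct")
  summaries |>
    dplyr::filter(.data$condition != "none") |>
    dplyr::inner_join(baseline, by = "participant") |>
    dplyr::left_join(jnds, by = "condition") |>
    dplyr::mutate(increase_ms = .data$mean_rt_correct -
                    .data$baseline_ms) |>
    dplyr::select("participant", "condition", "sc_jnd", "depth_jnd",
                  "jnd_total", "baseline_ms", "increase_ms")
}

#' Condition-level mean reaction-time increases
#'
#' Averages the per-participant increases within each singleton
#' condition; the standard error is across participants, matching how
#' condition error bars are usually reported.
#'
#' @param increases Output of [rt_increases()].
#' @return A tibble, one row per condition: `jnd_total`,
#'   `mean_increase_ms`, `se_ms`, `n_participants`.
#' @export
condition_increases <- function(increases) {
  increases |>
    dplyr::group_by(.data$condition, .data$sc_jnd, .data$depth_jnd,
                    .data$jnd_total) |>
    dplyr::summarise(
      mean_increase_ms = mean(.data$increase_ms),
      se_ms = sd(.data$increase_ms) / sqrt(dplyr::n()),
      n_participants = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$jnd_total)
}
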