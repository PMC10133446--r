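#' Simulate a full experiment at desk scale
#'
#' Builds the design's trial plan and runs a simulated cohort over it.
#'
#' @param experiment `"exp1"` ... `"exp5"`, or an
#'   [experiment_config()].
#' @param n_participants Cohort size; defaults to the published cohort
#'   of each design (15 for exp1, 20 for exp2/exp3, 19 for exp4/exp5).
#' @param population An [observer_population()].
#' @param seed Integer seed driving both the plan shuffle and the
#'   cohort.
#' @return A list: `config`, `plan`, `records`.
#' @export
#' @examples
#' sim <- simulate_experiment("exp1", n_participants = 3, seed = 1)
#' dim(sim$records)
simulate_experiment <- function(experiment, n_participants = NULL,
                                population = observer_population(),
                                seed = 1) {
  config <- if (inherits(experiment, "experiment_config")) experiment
            else experiment_config(experiment)
  if (is.null(n_participants)) {
    n_participants <- c(exp1 = 15L, exp2 = 20L, exp3 = 20L,
                        exp4 = 19L, exp5 = 19L)[[config$experiment]]
  }
  plan <- generate_plan(config, seed = seed)
  records <- simulate_cohort(plan, n_participants, population,
                             seed = seed)
  list(config = config, plan = plan, records = records)
}

#' Run the full analysis pipeline on a trial log
#'
#' Applies the participant exclusion rule and the trimming rules, then
#' computes per-cell summaries, reaction-time increases over the
#' no-singleton baseline, the singleton-presence paired t-test, the
#' per-variant tests with Holm correction, the position and surprise
#' tests, and (when at least 3 singleton conditions exist) the
#' regression of condition-mean reaction-time increase on total jnd
#' deviation.
#'
#' @param records A trial-record table ([simulate_cohort()] output or
#'   a CSV read with [read_trial_log()]).
#' @param floor_ms,k_sd Trimming parameters, see [clean_trials()].
#' @param max_error Participant exclusion threshold, see
#'   [exclude_participants()].
#' @param tail Tail for the paired tests (default two-sided).
#' @return A list of class `singleton_analysis`: `exclusions`,
#'   `cleaning`, `summaries`, `increases`, `by_condition`, `tests`,
#'   `position`, `surprise`, `regression` (NULL with < 3 conditions).
#' @export
analyze_experiment <- function(records, floor_ms = 100, k_sd = 2,
                               max_error = 0.40, tail = "two") {
  excl <- exclude_participants(records, max_error = max_error)
  cleaned <- clean_trials(excl$records, floor_ms = floor_ms, k_sd = k_sd)
  summaries <- summarize_conditions(cleaned$records)
  increases <- rt_increases(summaries, cleaned$records)
  by_condition <- condition_increases(increases)

  wide <- summaries |>
    dplyr::select("participant", "condition", "mean_rt_correct") |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = "mean_rt_correct")
  conds <- setdiff(unique(summaries$condition), "none")

  presence <- increases |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(increase = mean(.data$increase_ms),
                     .groups = "drop")
  tests <- paired_t(presence$increase, rep(0, nrow(presence)),
                    tail = tail, label = "singleton present - absent")
  per_variant <- dplyr::bind_rows(lapply(conds, function(cc) {
    ok <- stats::complete.cases(wide[[cc]], wide[["none"]])
    paired_t(wide[[cc]][ok], wide[["none"]][ok], tail = tail,
             label = paste0(cc, " - none"))
  }))
  per_variant <- holm_correct_tests(per_variant)

  regression <- if (nrow(by_condition) >= 3) {
    jnd_regression(by_condition$jnd_total, by_condition$mean_increase_ms)
  }

  structure(
    list(
      exclusions = excl$excluded, cleaning = cleaned$report,
      records = cleaned$records,
      summaries = summaries, increases = increases,
      by_condition = by_condition,
      tests = tests, per_variant = per_variant,
      position = tryCatch(position_effect(cleaned$records, tail = tail),
                          error = function(e) NULL),
      surprise = tryCatch(surprise_effect(cleaned$records, tail = tail),
                          error = function(e) NULL),
      regression = regression
    ),
    class = "singleton_analysis"
  )
}

#' @export
print.singleton_analysis <- function(x, ...) {
  print(x$cleaning)
  cat("\nMean RT increase by condition:\n")
  print(x$by_condition)
  cat(sprintf("\nSingleton presence: t(%d) = %.2f, p = %.2g, d = %.2f\n",
              x$tests$df, x$tests$t, x$tests$p_raw, x$tests$cohen_d))
  if (!is.null(x$regression)) {
    cat("\n")
    print(x$regression)
  }
  invisible(x)
}

#' Simulate a cohort and recover its capture slope
#'
#' End-to-end parameter recovery: simulates a cohort under the linear
#' capture law, runs the cleaning/summary pipeline, and regresses the
#' condition-mean reaction-time increases on the total jnd deviation.
#' For a brightness design the generating slope is the population's
#' brightness slope; for a roughness design, the roughness slope; for
#' the combined design, where both per-feature slopes are set equal
#' and costs add over the summed deviation, that common value.
#'
#' @inheritParams simulate_experiment
#' @param generating_slope Value of the per-feature slope(s) in
#'   ms/jnd applied to the features the design varies.
#' @param sigma_rt_ms Trial noise SD (ms).
#' @param n_participants Cohort size (default 20).
#' @return A list: `generating_slope`, `regression`, `recovered`
#'   (slope), `within_2se` (recovery check), `analysis`.
#' @export
#' @examples
#' \donttest{
#' recover_capture_slope("exp2", 14, seed = 1)$recovered
#' }
recover_capture_slope <- function(experiment, generating_slope,
                                  n_participants = 20, seed = 1,
                                  sigma_rt_ms = 150) {
  population <- observer_population(
    slope_brightness = generating_slope,
    slope_roughness = generating_slope,
    sigma_rt_ms = sigma_rt_ms
  )
  sim <- simulate_experiment(experiment, n_participants, population,
                             seed = seed)
  analysis <- analyze_experiment(sim$records)
  reg <- analysis$regression
  if (is.null(reg)) stop("design has fewer than 3 singleton conditions")
  list(
    generating_slope = generating_slope,
    regression = reg,
    recovered = reg$slope,
    within_2se = abs(reg$slope - generating_slope) <= 2 * reg$slope_se,
    analysis = analysis
  )
}

#' Read / write a trial-log CSV
#'
#' The on-disk schema matches [simulate_cohort()]'s columns, so
#' simulated logs and externally produced logs flow through the same
#' analysis.
#'
#' @param records A trial-record table.
#' @param path CSV path.
#' @return `read_trial_log()` returns the records tibble;
#'   `write_trial_log()` returns `path` invisibly.
#' @export
write_trial_log <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  needed <- c("participant", "condition", "target_kind", "response",
              "correct", "rt_ms", "sc_jnd", "depth_jnd", "jnd_total")
  missing <- setdiff(needed, names(out))
  if (length(missing)) {
    stop("trial log lacks required columns: ",
         paste(missing, collapse = ", "))
  }
  out$correct <- as.logical(out$correct)
  out
}

#' Reproduce one experiment end to end
#'
#' Plan, simulate, analyze, and write all artifacts (config snapshot,
#' plan, trial log, cleaning report, condition summaries, tests,
#' regression, figures, and optionally the tone-bank audio) under
#' `out_dir`.
#'
#' @inheritParams simulate_experiment
#' @param out_dir Output directory.
#' @param write_audio Also synthesize and write the tone bank WAVs.
#' @param figures Write the condition and capture-law figures (PDF).
#' @return The `singleton_analysis`, invisibly.
#' @export
reproduce_experiment <- function(experiment, seed = 1,
                                 out_dir = ".",
                                 n_participants = NULL,
                                 population = observer_population(),
                                 write_audio = FALSE, figures = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_experiment(experiment, n_participants, population,
                             seed = seed)
  analysis <- analyze_experiment(sim$records)

  cfg <- sim$config
  cfg_out <- cfg[!vapply(cfg, inherits, logical(1), "feature_ladder")]
  cfg_out$seed <- seed
  jsonlite::write_json(cfg_out, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.csv(sim$plan, file.path(out_dir, "plan.csv"), row.names = FALSE)
  write_trial_log(sim$records, file.path(out_dir, "trials.csv"))
  write.csv(analysis$summaries, file.path(out_dir, "summaries.csv"),
            row.names = FALSE)
  write.csv(analysis$by_condition, file.path(out_dir, "increases.csv"),
            row.names = FALSE)
  write.csv(dplyr::bind_rows(analysis$tests, analysis$per_variant),
            file.path(out_dir, "tests.csv"), row.names = FALSE)
  jsonlite::write_json(
    c(list(kept_fraction_all = analysis$cleaning$kept_fraction_all,
           kept_fraction_correct = analysis$cleaning$kept_fraction_correct),
      as.list(analysis$cleaning$removed_by_rule)),
    file.path(out_dir, "cleaning.json"), auto_unbox = TRUE, digits = NA
  )
  if (!is.null(analysis$regression)) {
    jsonlite::write_json(unclass(analysis$regression),
                         file.path(out_dir, "regression.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (figures) {
    ggplot2::ggsave(file.path(out_dir, "increase_by_condition.pdf"),
                    plot_increases(analysis$by_condition),
                    width = 6, height = 4)
    if (!is.null(analysis$regression)) {
      ggplot2::ggsave(file.path(out_dir, "capture_law.pdf"),
                      plot_capture_law(analysis$by_condition,
                                       analysis$regression),
                      width = 6, height = 4)
    }
  }
  if (write_audio) {
    write_tone_bank(build_tone_bank(sim$config),
                    file.path(out_dir, "audio"), rate = sim$config$rate)
  }
  invisible(analysis)
}

#' Plot condition-mean reaction-time increases
#'
#' @param by_condition Output of [condition_increases()].
#' @return A ggplot.
#' @export
plot_increases <- function(by_condition) {
  ggplot2::ggplot(
    by_condition,
    ggplot2::aes(x = stats::reorder(.data$condition, .data$jnd_total),
                 y = .data$mean_increase_ms)
  ) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_increase_ms - .data$se_ms,
                   ymax = .data$mean_increase_ms + .data$se_ms),
      width = 0.2
    ) +
    ggplot2::labs(x = "singleton condition",
                  y = "RT increase vs no singleton (ms)") +
    ggplot2::theme_minimal()
}

#' Plot the fitted capture law
#'
#' @param by_condition Output of [condition_increases()].
#' @param regression A [jnd_regression()] fit.
#' @return A ggplot.
#' @export
plot_capture_law <- function(by_condition, regression) {
  ggplot2::ggplot(by_condition,
                  ggplot2::aes(x = .data$jnd_total,
                               y = .data$mean_increase_ms)) +
    ggplot2::geom_abline(intercept = regression$intercept,
                         slope = regression$slope, color = "steelblue") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_increase_ms - .data$se_ms,
                   ymax = .data$mean_increase_ms + .data$se_ms)
    ) +
    ggplot2::labs(
      x = "perceived feature deviation (jnd)",
      y = "RT increase (ms)",
      subtitle = sprintf("slope %.1f ms/jnd (se %.1f), r = %.3f",
                         regression$slope, regression$slope_se,
                         regression$pearson_r)
    ) +
    ggplot2::theme_minimal()
}
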