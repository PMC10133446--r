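#' Linear Integrated Speed-Accuracy Score for one condition cell
#'
#' `LISAS = mean correct RT + (SD of correct RTs / SD of the binary
#' error indicator) * error proportion`, with sample SDs computed
#' within the cell. When the error SD is zero (all correct or all
#' wrong with at least one correct trial) the score reduces to the
#' mean correct reaction time.
#'
#' @param rt_ms Reaction times of the cell's answered trials (ms).
#' @param correct Logical vector, same length.
#' @return The score in ms.
#' @export
#' @examples
#' lisas(rep(1000, 4), c(TRUE, TRUE, TRUE, TRUE))  # 1000
lisas <- function(rt_ms, correct) {
  stopifnot(length(rt_ms) == length(correct), length(rt_ms) >= 1)
  if (!any(correct)) stop("LISAS needs at least one correct trial")
  rt_c <- rt_ms[correct]
  mean_rt <- mean(rt_c)
  if (length(rt_c) < 2 || length(correct) < 2) return(mean_rt)
  s_rt <- sd(rt_c)
  s_err <- sd(!correct)
  pe <- mean(!correct)
  if (s_err == 0 || is.na(s_err)) return(mean_rt)
  mean_rt + (s_rt / s_err) * pe
}

#' Paired t-test with Cohen's d
#'
#' @param x,y Matched per-participant values (same order).
#' @param tail `"two"` (default), `"greater"` or `"less"`, testing
#'   `x - y` in the stated direction.
#' @param label Comparison label carried into the result.
#' @return A one-row tibble: `comparison`, `t`, `df`, `p_raw`,
#'   `cohen_d`, `mean_diff`, `n` (a `p_holm` column is added by
#'   [holm_correct_tests()]).
#' @export
#' @examples
#' paired_t(c(110, 120, 130, 140), c(100, 100, 100, 100))
paired_t <- function(x, y, tail = c("two", "greater", "less"),
                     label = "x - y") {
  tail <- match.arg(tail)
  stopifnot(length(x) == length(y))
  if (length(x) < 2) stop("paired t-test needs at least 2 pairs")
  alt <- switch(tail, two = "two.sided", greater = "greater",
                less = "less")
  d <- x - y
  if (sd(d) == 0) {
    # zero-variance differences: the t statistic diverges (or is 0)
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else {
      dir_p <- switch(tail, two = 0, greater = if (mean(d) > 0) 0 else 1,
                      less = if (mean(d) < 0) 0 else 1)
      dir_p
    }
    return(tibble::tibble(
      comparison = label, t = t_stat, df = length(d) - 1, p_raw = p,
      cohen_d = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
      mean_diff = mean(d), n = length(d)
    ))
  }
  ht <- t.test(x, y, paired = TRUE, alternative = alt)
  tibble::tibble(
    comparison = label,
    t = unname(ht$statistic),
    df = unname(ht$parameter),
    p_raw = ht$p.value,
    cohen_d = mean(d) / sd(d),
    mean_diff = mean(d),
    n = length(d)
  )
}

#' Holm step-down adjustment
#'
#' Step-down Holm correction with monotonicity enforcement, mapped
#' back to the input order. `holm_correct_tests()` applies it to the
#' `p_raw` column of a table of [paired_t()] results.
#'
#' @param p Raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same order.
#' @export
#' @examples
#' holm_correct(c(0.005, 0.01, 0.03, 0.04))  # 0.02 0.03 0.06 0.06
holm_correct <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "holm")
}

#' @rdname holm_correct
#' @param tests A tibble with a `p_raw` column.
#' @export
holm_correct_tests <- function(tests) {
  tests$p_holm <- holm_correct(tests$p_raw)
  tests
}

#' Minimum sample size for a paired/one-sample t-test
#'
#' Smallest integer `n` whose noncentral-t power reaches the target:
#' with `df = n - 1` and noncentrality `d * sqrt(n)`, power is the
#' probability that the t statistic exceeds the critical value.
#'
#' @param d Effect size (Cohen's d, > 0).
#' @param alpha Significance level.
#' @param power Target power.
#' @param tail `"one"` or `"two"`.
#' @param n_max Search bound.
#' @return Minimum sample size (integer).
#' @export
#' @examples
#' power_sample_size(0.8, 0.05, 0.8, "one")  # 12
power_sample_size <- function(d, alpha = 0.05, power = 0.8,
                              tail = c("one", "two"), n_max = 1e5) {
  tail <- match.arg(tail)
  if (d <= 0) stop("effect size `d` must be positive")
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1)
  for (n in 2:n_max) {
    df <- n - 1
    ncp <- d * sqrt(n)
    pw <- if (tail == "one") {
      1 - pt(qt(1 - alpha, df), df, ncp)
    } else {
      crit <- qt(1 - alpha / 2, df)
      1 - pt(crit, df, ncp) + pt(-crit, df, ncp)
    }
    if (pw >= power) return(n)
  }
  stop("no n up to ", n_max, " reaches the requested power")
}

#' Regress reaction-time cost on perceived feature deviation
#'
#' Ordinary least squares of the mean reaction-time increase on the
#' deviation in jnd: the fitted slope is the capture law's weight in
#' ms per jnd.
#'
#' @param jnd Perceived deviations (jnd); at least 3 points.
#' @param increase_ms Mean reaction-time increases (ms).
#' @return A list of class `jnd_regression`: `slope`, `slope_se`,
#'   `intercept`, `pearson_r`, `n_points`, `degenerate` (TRUE when the
#'   response is constant, in which case the slope is 0 and r is NA).
#' @export
#' @examples
#' jnd_regression(c(1, 2, 5, 10), 14 * c(1, 2, 5, 10))
jnd_regression <- function(jnd, increase_ms) {
  stopifnot(length(jnd) == length(increase_ms))
  if (length(jnd) < 3) stop("regression needs at least 3 points")
  if (sd(increase_ms) == 0) {
    out <- list(slope = 0, slope_se = 0, intercept = increase_ms[1],
                pearson_r = NA_real_, n_points = length(jnd),
                degenerate = TRUE)
    return(structure(out, class = "jnd_regression"))
  }
  fit <- lm(increase_ms ~ jnd)
  sxx <- sum((jnd - mean(jnd))^2)
  s2 <- sum(stats::residuals(fit)^2) / (length(jnd) - 2)
  structure(
    list(slope = unname(coef(fit)[2]), slope_se = sqrt(s2 / sxx),
         intercept = unname(coef(fit)[1]),
         pearson_r = cor(jnd, increase_ms),
         n_points = length(jnd), degenerate = FALSE),
    class = "jnd_regression"
  )
}

#' @export
print.jnd_regression <- function(x, ...) {
  cat(sprintf(
    "<jnd_regression> slope = %.2f ms/jnd (se %.2f), intercept %.1f ms, r = %.4f, %d points\n",
    x$slope, x$slope_se, x$intercept,
    ifelse(is.na(x$pearson_r), NaN, x$pearson_r), x$n_points
  ))
  invisible(x)
}

#' Singleton position effect on reaction times
#'
#' Paired t-test of per-participant mean correct reaction times on
#' singleton trials with the singleton after versus before the target.
#'
#' @param records Cleaned trial records with `singleton_pos` labels.
#' @param tail Test tail, as in [paired_t()].
#' @return A one-row [paired_t()] result.
#' @export
position_effect <- function(records, tail = "two") {
  sing <- dplyr::filter(records, !is.na(.data$singleton_pos),
                        .data$correct)
  if (nrow(sing) == 0) stop("no singleton trials with position labels")
  means <- sing |>
    dplyr::group_by(.data$participant, .data$singleton_pos) |>
    dplyr::summarise(rt = mean(.data$rt_ms), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "singleton_pos", values_from = "rt") |>
    tidyr::drop_na()
  paired_t(means$after, means$before, tail = tail,
           label = "singleton after - before")
}

#' Surprise effect on reaction times
#'
#' Compares singleton trials preceded (in each participant's
#' presentation order) by a singleton-absent trial ("surprising")
#' against those preceded by a singleton trial ("non-surprising"),
#' by paired t-test on per-participant mean correct reaction times.
#'
#' @param records Cleaned trial records with `presentation` order and
#'   `condition` labels.
#' @param tail Test tail, as in [paired_t()].
#' @return A one-row [paired_t()] result.
#' @export
surprise_effect <- function(records, tail = "two") {
  if (!"presentation" %in% names(records)) {
    stop("records need a `presentation` (within-participant order) column")
  }
  hist <- records |>
    dplyr::group_by(.data$participant) |>
    dplyr::arrange(.data$presentation, .by_group = TRUE) |>
    dplyr::mutate(prev_none =
                    dplyr::lag(.data$condition) == "none") |>
    dplyr::ungroup() |>
    dplyr::filter(.data$condition != "none", .data$correct,
                  !is.na(.data$prev_none))
  means <- hist |>
    dplyr::group_by(.data$participant, .data$prev_none) |>
    dplyr::summarise(rt = mean(.data$rt_ms), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "prev_none", values_from = "rt",
                       names_prefix = "prev_none_") |>
    tidyr::drop_na()
  paired_t(means$prev_none_TRUE, means$prev_none_FALSE, tail = tail,
           label = "surprising - non-surprising")
}
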