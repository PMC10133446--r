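test_that("2-SD trimming removes exactly what the hand-worked band excludes", {
  rts <- c(seq(480, 560, by = 10), 2000)
  # oracle: one-pass band from plain mean/SD arithmetic
  band <- mean(rts) + c(-2, 2) * sd(rts)
  expect_true(2000 > band[2])            # the outlier falls outside
  expect_true(all(rts[rts != 2000] >= band[1] & rts[rts != 2000] <= band[2]))
  rec <- make_records(1, "none", rts)
  out <- clean_trials(rec)
  expect_setequal(out$records$rt_ms, setdiff(rts, 2000))
  expect_equal(unname(out$report$removed_by_rule["sd"]), 1)
  expect_equal(out$report$kept_fraction_all, 9 / 10)
})

test_that("identical reaction times are never trimmed by the SD rule", {
  rec <- make_records(1, "none", rep(700, 8))
  out <- suppressWarnings(clean_trials(rec))
  expect_equal(nrow(out$records), 8)
})

test_that("floor and no-answer rules apply before the SD band", {
  rec <- make_records(1, "none", c(90, rep(700, 6), NA))
  rec$response[8] <- "none"
  rec$correct[8] <- FALSE
  out <- clean_trials(rec)
  expect_equal(unname(out$report$removed_by_rule),
               c(1, 1, 0))  # no-answer, floor, sd
  expect_equal(nrow(out$records), 6)
})

test_that("tiny cells pass through untrimmed with a warning", {
  rec <- make_records(1, "none", c(500, 5000))
  expect_warning(out <- clean_trials(rec), "fewer than 3")
  expect_equal(nrow(out$records), 2)
})

test_that("participants at or above 40% errors are excluded", {
  rec <- dplyr::bind_rows(
    make_records(1, "none", rep(700, 10),
                 correct = rep(c(TRUE, FALSE), 5)),            # 50%
    make_records(2, "none", rep(700, 10),
                 correct = rep(c(TRUE, TRUE, TRUE, FALSE, FALSE), 2)), # 40%
    make_records(3, "none", rep(700, 10))                      # perfect
  )
  out <- exclude_participants(rec)
  expect_setequal(out$excluded$participant, c(1, 2))
  expect_setequal(unique(out$records$participant), 3)
  perfect <- exclude_participants(make_records(4, "none", rep(700, 5)))
  expect_equal(nrow(perfect$excluded), 0)
})

test_that("LISAS equals its hand-worked value and degenerates to mean RT", {
  z <- 1:12 - 6.5
  rt_correct <- 1000 + 100 * z / sd(z)     # mean 1000, sample SD 100
  rt <- c(rt_correct, rep(800, 4))
  correct <- rep(c(TRUE, FALSE), c(12, 4))
  expect_equal(lisas(rt, correct),
               1000 + (100 / sd(rep(c(1, 0), c(4, 12)))) * 0.25)
  expect_equal(lisas(rt, correct), 1055.902, tolerance = 1e-4)
  expect_equal(lisas(rt_correct, rep(TRUE, 12)), 1000)
  # linear in the reaction-time scale when the error structure is fixed
  expect_equal(lisas(2 * rt, correct), 2 * lisas(rt, correct))
  expect_error(lisas(c(500, 600), c(FALSE, FALSE)), "correct")
})

test_that("paired t-test and Cohen's d match the hand computation", {
  x <- c(110, 120, 130, 140)
  y <- rep(100, 4)
  res <- paired_t(x, y)
  expect_equal(res$t, 25 / (sd(x - y) / 2))
  expect_equal(res$t, 3.873, tolerance = 1e-3)
  expect_equal(res$cohen_d, 1.936, tolerance = 1e-3)
  expect_equal(res$df, 3)
  sym <- paired_t(c(-10, 10, -20, 20), rep(0, 4))
  expect_equal(sym$t, 0)
  expect_equal(sym$p_raw, 1)
  expect_error(paired_t(1, 2), "at least 2")
})

test_that("Holm adjustment matches the step-down hand example", {
  expect_equal(holm_correct(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.03, 0.06, 0.06))
  expect_equal(holm_correct(0.2), 0.2)
  expect_equal(holm_correct(rep(1, 5)), rep(1, 5))
  # pointwise >= raw, and permutation-equivariant
  withr::with_seed(1, {
    for (i in 1:10) {
      p <- runif(6)
      adj <- holm_correct(p)
      expect_true(all(adj >= p))
      perm <- sample(6)
      expect_equal(holm_correct(p[perm]), adj[perm])
    }
  })
})

test_that("power analysis reproduces the published minimum sample size", {
  expect_identical(power_sample_size(0.8, 0.05, 0.8, "one"), 12L)
  expect_identical(power_sample_size(2.1, 0.05, 0.8, "one"), 4L)
  expect_error(power_sample_size(-1), "positive")
  # monotone: more power never needs fewer participants
  ns <- vapply(c(0.5, 0.8, 0.9, 0.95),
               function(pw) power_sample_size(0.8, 0.05, pw, "one"),
               integer(1))
  expect_true(all(diff(ns) >= 0))
  # independent route: continuous solution from power.t.test, ceiled
  for (d in c(0.5, 0.8, 1.0, 2.1)) {
    ref <- ceiling(stats::power.t.test(
      delta = d, sd = 1, sig.level = 0.05, power = 0.8,
      type = "one.sample", alternative = "one.sided")$n)
    expect_equal(power_sample_size(d, 0.05, 0.8, "one"), as.integer(ref))
  }
})

test_that("the jnd regression matches closed-form least squares", {
  exact <- jnd_regression(c(1, 2, 5, 10), 14 * c(1, 2, 5, 10))
  expect_equal(exact$slope, 14)
  expect_equal(exact$slope_se, 0, tolerance = 1e-10)
  expect_equal(exact$pearson_r, 1)

  x <- c(1, 2, 5, 10); y <- c(10, 32, 68, 143)
  # closed-form oracle
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  fit <- jnd_regression(x, y)
  expect_equal(fit$slope, sxy / sxx)
  expect_equal(fit$slope, 14.39796, tolerance = 1e-5)
  expect_equal(fit$pearson_r, 0.9981842, tolerance = 1e-6)
  s2 <- (sum((y - mean(y))^2) - (sxy / sxx) * sxy) / 2
  expect_equal(fit$slope_se, sqrt(s2 / sxx))

  flat <- jnd_regression(c(1, 2, 5), rep(30, 3))
  expect_true(flat$degenerate)
  expect_equal(flat$slope, 0)
  expect_true(is.na(flat$pearson_r))
  expect_error(jnd_regression(1:2, 1:2), "at least 3")
})

test_that("cleaning removes exactly the floor/timeout violations when noise-free", {
  plan <- generate_plan(experiment_config("exp1"), seed = 6)
  p <- observer_params(sigma_rt_ms = 0, base_error_rate = 0,
                       error_capture_gain = 0, lapse_rate = 0)
  rec <- simulate_trials(plan, p)
  rec$rt_ms[c(3, 50)] <- 60                 # anticipations
  rec$response[c(7, 80)] <- "none"          # deadline misses
  rec$rt_ms[c(7, 80)] <- NA
  rec$correct[c(7, 80)] <- FALSE
  rec$participant <- 1
  out <- clean_trials(rec)
  expect_equal(unname(out$report$removed_by_rule), c(2, 2, 0))
  expect_equal(nrow(out$records), nrow(rec) - 4)
})

test_that("an injected position cost is detected and a null one is not", {
  plan <- generate_plan(experiment_config("exp1"), seed = 10)
  with_pos <- observer_population(mu_rt_sd = 0, position_effect_ms = 50)
  rec <- simulate_cohort(plan, 12, with_pos, seed = 21)
  eff <- position_effect(clean_trials(rec)$records)
  expect_gt(eff$mean_diff, 20)
  expect_lt(eff$p_raw, 0.01)

  no_pos <- observer_population(mu_rt_sd = 0, position_effect_ms = 0)
  rec0 <- simulate_cohort(plan, 12, no_pos, seed = 21)
  eff0 <- position_effect(clean_trials(rec0)$records)
  expect_lt(abs(eff0$mean_diff), 25)
})

test_that("a history-free observer shows no surprise effect", {
  plan <- generate_plan(experiment_config("exp1"), seed = 10)
  rec <- simulate_cohort(plan, 12, observer_population(mu_rt_sd = 0),
                         seed = 22)
  eff <- surprise_effect(clean_trials(rec)$records)
  expect_lt(abs(eff$mean_diff), 25)
  expect_gt(eff$p_raw, 0.01)
})
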