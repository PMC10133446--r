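#' Generative observer parameters
#'
#' One simulated participant responds "short" or "long" to the target
#' duration. The reaction time, measured from target onset, is
#' `mu_rt_ms + capture_cost + noise`: the attentional-capture cost is
#' linear in the singleton's absolute perceived deviation,
#' `slope_brightness * |jnd_b| + slope_roughness * |jnd_r|`, symmetric
#' in sign and additive across the two timbre features. Noise is
#' zero-mean Gaussian truncated below at 0; draws at or beyond
#' `timeout_ms` become missing responses. Errors occur with
#' probability `base_error_rate + error_capture_gain * total jnd`
#' (clipped to `[0, 1]`), mirroring error rates that track the
#' reaction-time cost; on a lapse the response is random and the
#' reaction time uniform over the response window.
#'
#' @param mu_rt_ms Baseline mean correct reaction time, no singleton
#'   (ms).
#' @param sigma_rt_ms Trial-to-trial reaction-time noise SD (ms).
#' @param slope_brightness Capture cost per brightness jnd (ms/jnd).
#' @param slope_roughness Capture cost per roughness jnd (ms/jnd).
#' @param base_error_rate Error probability without a singleton.
#' @param error_capture_gain Added error probability per total jnd.
#' @param lapse_rate Probability of a random response with uniform
#'   reaction time.
#' @param position_effect_ms Extra cost when the singleton follows the
#'   target (0 by default).
#' @param timeout_ms Response deadline from target onset (3000 ms).
#' @param rt_floor_ms Analysis floor, carried for bookkeeping (100 ms).
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(mu_rt_ms = 985, sigma_rt_ms = 150,
                            slope_brightness = 14, slope_roughness = 12.4,
                            base_error_rate = 0.162,
                            error_capture_gain = 0.0066,
                            lapse_rate = 0.02, position_effect_ms = 0,
                            timeout_ms = 3000, rt_floor_ms = 100) {
  stopifnot(mu_rt_ms > rt_floor_ms, sigma_rt_ms >= 0,
            slope_brightness >= 0, slope_roughness >= 0,
            base_error_rate >= 0, base_error_rate <= 1,
            error_capture_gain >= 0,
            lapse_rate >= 0, lapse_rate <= 1, timeout_ms > 0)
  structure(
    list(mu_rt_ms = mu_rt_ms, sigma_rt_ms = sigma_rt_ms,
         slope_brightness = slope_brightness,
         slope_roughness = slope_roughness,
         base_error_rate = base_error_rate,
         error_capture_gain = error_capture_gain,
         lapse_rate = lapse_rate, position_effect_ms = position_effect_ms,
         timeout_ms = timeout_ms, rt_floor_ms = rt_floor_ms),
    class = "observer_params"
  )
}

#' Expected attentional-capture cost of each planned trial
#'
#' `slope_brightness * |sc_jnd| + slope_roughness * |depth_jnd|`, and 0
#' for singleton-absent trials; the sign of a deviation never matters
#' and the two features add.
#'
#' @param plan A [generate_plan()] table (or any data frame with
#'   `sc_jnd` and `depth_jnd` columns).
#' @param params An [observer_params()].
#' @return Numeric vector of expected costs in ms, one per trial.
#' @export
#' @examples
#' p <- observer_params(slope_brightness = 14)
#' capture_cost(data.frame(sc_jnd = c(0, -2, 2), depth_jnd = 0), p)
capture_cost <- function(plan, params) {
  stopifnot(inherits(params, "observer_params"))
  params$slope_brightness * abs(plan$sc_jnd) +
    params$slope_roughness * abs(plan$depth_jnd)
}

#' Simulate one participant's responses to a trial plan
#'
#' Uses the current RNG state; seed management belongs to the caller
#' (see [simulate_cohort()] for the reproducible entry point).
#'
#' @param plan A [generate_plan()] table.
#' @param params An [observer_params()].
#' @return A tibble of trial records: the plan columns plus `response`
#'   (`"short"`, `"long"`, `"none"`), `correct`, and `rt_ms` (NA when
#'   no response was given before the deadline).
#' @export
simulate_trials <- function(plan, params) {
  stopifnot(inherits(params, "observer_params"))
  n <- nrow(plan)
  cost <- capture_cost(plan, params)
  if (params$position_effect_ms != 0) {
    after <- !is.na(plan$singleton_pos) & plan$singleton_pos == "after"
    cost <- cost + params$position_effect_ms * after
  }
  rt <- rnorm(n, params$mu_rt_ms + cost, params$sigma_rt_ms)
  rt <- pmax(rt, 0)

  p_err <- pmin(1, pmax(0, params$base_error_rate +
                          params$error_capture_gain * plan$jnd_total))
  err <- runif(n) < p_err
  other <- ifelse(plan$target_kind == "short", "long", "short")
  response <- ifelse(err, other, plan$target_kind)

  lapse <- runif(n) < params$lapse_rate
  if (any(lapse)) {
    rt[lapse] <- runif(sum(lapse), 0, params$timeout_ms)
    response[lapse] <- sample(c("short", "long"), sum(lapse),
                              replace = TRUE)
  }

  timed_out <- rt >= params$timeout_ms
  response[timed_out] <- "none"
  rt[timed_out] <- NA_real_

  out <- tibble::as_tibble(plan)
  out$response <- response
  out$correct <- !is.na(response) & response == plan$target_kind
  out$rt_ms <- rt
  out
}

#' Population distribution of observer parameters
#'
#' Per-participant parameters are drawn independently: the baseline
#' reaction time from a normal distribution (truncated above the
#' reaction-time floor), the capture slopes from normals truncated at
#' 0. Zero SDs give a homogeneous cohort. Defaults place the baseline
#' around 985 ms with a 140 ms between-participant SD and use the
#' linear-law slopes of 14 ms/jnd (brightness) and 12.4 ms/jnd
#' (roughness).
#'
#' @param mu_rt_mean,mu_rt_sd Between-participant distribution of the
#'   baseline reaction time (ms).
#' @param slope_brightness,slope_brightness_sd Brightness slope
#'   distribution (ms/jnd).
#' @param slope_roughness,slope_roughness_sd Roughness slope
#'   distribution (ms/jnd).
#' @param ... Remaining [observer_params()] fields, identical across
#'   participants.
#' @return An object of class `observer_population`.
#' @export
observer_population <- function(mu_rt_mean = 985, mu_rt_sd = 140,
                                slope_brightness = 14,
                                slope_brightness_sd = 0,
                                slope_roughness = 12.4,
                                slope_roughness_sd = 0, ...) {
  structure(
    list(mu_rt_mean = mu_rt_mean, mu_rt_sd = mu_rt_sd,
         slope_brightness = slope_brightness,
         slope_brightness_sd = slope_brightness_sd,
         slope_roughness = slope_roughness,
         slope_roughness_sd = slope_roughness_sd,
         fixed = list(...)),
    class = "observer_population"
  )
}

draw_participant_params <- function(population) {
  tnorm <- function(mean, sd, lower) {
    if (sd == 0) return(mean)
    x <- rnorm(1, mean, sd)
    while (x <= lower) x <- rnorm(1, mean, sd)
    x
  }
  floor_ms <- population$fixed$rt_floor_ms %||% 100
  args <- c(
    list(
      mu_rt_ms = tnorm(population$mu_rt_mean, population$mu_rt_sd,
                       floor_ms),
      slope_brightness = tnorm(population$slope_brightness,
                               population$slope_brightness_sd, 0),
      slope_roughness = tnorm(population$slope_roughness,
                              population$slope_roughness_sd, 0)
    ),
    population$fixed
  )
  do.call(observer_params, args)
}

#' Simulate a cohort of participants
#'
#' Each participant gets parameters drawn from the population, an
#' independently shuffled presentation order of the same plan, and a
#' participant-specific RNG stream derived from `seed`, so the full
#' trial log is reproducible from `(plan, population, seed)`.
#'
#' @param plan A [generate_plan()] table.
#' @param n_participants Number of simulated participants.
#' @param population An [observer_population()].
#' @param seed Integer seed.
#' @return A tibble of trial records with `participant` and
#'   `presentation` (within-participant presentation order) columns
#'   prepended; the generating population and seed are attached as
#'   attributes.
#' @export
#' @examples
#' plan <- generate_plan(experiment_config("exp1"), seed = 1)
#' recs <- simulate_cohort(plan, n_participants = 2,
#'                         observer_population(), seed = 1)
#' nrow(recs)  # 720
simulate_cohort <- function(plan, n_participants,
                            population = observer_population(), seed) {
  stopifnot(inherits(population, "observer_population"),
            n_participants >= 1)
  out <- lapply(seq_len(n_participants), function(i) {
    p_seed <- (seed + 104729 * i) %% .Machine$integer.max
    withr::with_seed(p_seed, {
      params <- draw_participant_params(population)
      shuffled <- plan[sample.int(nrow(plan)), ]
      rec <- simulate_trials(shuffled, params)
      rec$participant <- i
      rec$presentation <- seq_len(nrow(rec))
      rec
    })
  })
  out <- dplyr::bind_rows(out)
  out <- dplyr::relocate(out, "participant", "presentation")
  attr(out, "population") <- population
  attr(out, "seed") <- seed
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
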