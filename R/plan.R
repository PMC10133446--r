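#' Configuration for one additional-singleton experiment
#'
#' Returns the full parameter set of one of the five packaged designs.
#' All stimulus constants live here, not in the synthesis or analysis
#' logic: 170 ms distractors, 120/220 ms short/long targets, 5 ms
#' ramps, 230 ms inter-onset interval, 3000 ms response timeout, the
#' 5% centroid jnd and 10% depth jnd, the loudness-equalized levels
#' (metadata), and each design's singleton variant table.
#'
#' Designs:
#' * `exp1` — single bright singleton (centroid 822 Hz vs 512 Hz
#'   distractors), present on 50% of trials; 6 blocks of 60.
#' * `exp2` — centroid ladder 538/563/640/768 Hz (additive 5% steps
#'   times 1/2/5/10 from 512 Hz); 8 blocks of 80, each variant 20%.
#' * `exp3` — roughness ladder, modulation depths 0.1/0.2/0.5/1.0
#'   (10% steps times 1/2/5/10); 8 blocks of 80.
#' * `exp4` — distractor centroid 631 Hz; singletons 2 or 4 jnd above
#'   or below (512/569/696/768 Hz, the published values taken
#'   verbatim); 8 blocks of 80.
#' * `exp5` — compound brightness (2 or 5 jnd above 512 Hz: 564/653
#'   Hz) crossed with roughness (depth 0.2 or 0.5), summed deviations
#'   4/7/7/10 jnd; 8 blocks of 80.
#'
#' The nominal fundamental is chosen so that a slope exponent of 3
#' gives the 512 Hz distractor centroid (about 385.2 Hz); per-trial
#' fundamentals are jittered uniformly over a configurable total width
#' (20 Hz by default), and singleton exponents are always obtained by
#' inverting the centroid formula at the trial's fundamental.
#'
#' @param experiment One of `"exp1"` ... `"exp5"`.
#' @param ... Named overrides of any configuration field.
#' @return A list of class `experiment_config`.
#' @export
#' @examples
#' experiment_config("exp2")$variants
experiment_config <- function(experiment = c("exp1", "exp2", "exp3",
                                             "exp4", "exp5"), ...) {
  experiment <- match.arg(experiment)
  n_harmonics <- 20L
  sc_jnd <- 0.05
  depth_jnd <- 0.10
  # fundamental such that alpha = 3 yields a 512 Hz centroid
  f0_nominal <- 512 / (spectral_centroid(3, 1, n_harmonics))

  variant_tbl <- function(label, sc_hz, sc_jnd_dev, depth, depth_jnd_dev) {
    tibble::tibble(
      condition = label, sc_hz = sc_hz, sc_jnd = sc_jnd_dev,
      am_depth = depth, depth_jnd = depth_jnd_dev
    )
  }

  cfg <- switch(
    experiment,
    exp1 = list(
      base_sc_hz = 512, n_blocks = 6L, block_size = 60L,
      singleton_share = 0.5,
      # the bright singleton's centroid, published as 822 Hz; its
      # deviation on the 5%-jnd ladder scale is (822/512 - 1) / 0.05
      variants = variant_tbl("sc822", 822, (822 / 512 - 1) / sc_jnd, 0, 0),
      levels_db = c(distractor = 80, target_short = 81, target_long = 79,
                    sc822 = 74)
    ),
    exp2 = {
      lad <- feature_ladder("brightness_sc", 512, sc_jnd, c(1, 2, 5, 10),
                            "additive")
      sc <- build_ladder(lad)
      list(
        base_sc_hz = 512, n_blocks = 8L, block_size = 80L,
        singleton_share = 0.8, ladder = lad,
        variants = variant_tbl(paste0("sc", round(sc)), sc,
                               c(1, 2, 5, 10), 0, 0),
        levels_db = c(distractor = 80, target_short = 81, target_long = 79,
                      sc538 = 79.5, sc563 = 79, sc640 = 77.5, sc768 = 75)
      )
    },
    exp3 = {
      lad <- feature_ladder("roughness_depth", 0, depth_jnd, c(1, 2, 5, 10),
                            "additive")
      m <- build_ladder(lad)
      list(
        base_sc_hz = 512, n_blocks = 8L, block_size = 80L,
        singleton_share = 0.8, ladder = lad,
        variants = variant_tbl(sprintf("am%.1f", m), NA_real_, 0,
                               m, c(1, 2, 5, 10)),
        levels_db = c(distractor = 80, target_short = 81, target_long = 79,
                      am0.1 = 80, am0.2 = 80, am0.5 = 80, am1.0 = 80)
      )
    },
    exp4 = list(
      base_sc_hz = 631, n_blocks = 8L, block_size = 80L,
      singleton_share = 0.8,
      # published centroids taken verbatim; deviations are +/-2, +/-4 jnd
      variants = variant_tbl(paste0("sc", c(512, 569, 696, 768)),
                             c(512, 569, 696, 768),
                             c(-4, -2, 2, 4), 0, 0),
      levels_db = c(distractor = 78, target_short = 78, target_long = 78,
                    sc512 = 80, sc569 = 79, sc696 = 77, sc768 = 75)
    ),
    exp5 = {
      lad <- feature_ladder("brightness_sc", 512, sc_jnd, c(2, 5),
                            "compound")
      sc <- build_ladder(lad)
      m <- build_ladder(feature_ladder("roughness_depth", 0, depth_jnd,
                                       c(2, 5), "additive"))
      combos <- expand.grid(b = 1:2, r = 1:2)
      list(
        base_sc_hz = 512, n_blocks = 8L, block_size = 80L,
        singleton_share = 0.8, ladder = lad,
        variants = variant_tbl(
          sprintf("sc%d_am%.1f", round(sc)[combos$b], m[combos$r]),
          sc[combos$b], c(2, 5)[combos$b],
          m[combos$r], c(2, 5)[combos$r]
        ),
        levels_db = c(distractor = 80, target_short = 81, target_long = 79)
      )
    }
  )

  out <- c(
    list(
      experiment = experiment,
      f0_nominal_hz = f0_nominal, f0_jitter_hz = 20,
      n_harmonics = n_harmonics,
      sc_jnd_fraction = sc_jnd, depth_jnd_fraction = depth_jnd,
      distractor_ms = 170, target_short_ms = 120, target_long_ms = 220,
      ramp_ms = 5, ioi_ms = 230, am_freq_hz = 50,
      timeout_ms = 3000, rt_floor_ms = 100,
      rate = 44100
    ),
    cfg
  )
  dots <- list(...)
  out[names(dots)] <- dots
  structure(out, class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    "<experiment_config> %s: %d blocks x %d trials, singleton share %.0f%%\n",
    x$experiment, x$n_blocks, x$block_size, 100 * x$singleton_share
  ))
  print(x$variants)
  invisible(x)
}

#' Generate a balanced, shuffled trial plan
#'
#' Within every block the marginal balance constraints hold exactly:
#' short/long targets 50/50, target position 3/4 50/50, the singleton
#' conditions (including "none") at their configured shares, and
#' before/after singleton placement 50/50 within every singleton
#' variant. The first sequence slot is always a distractor by
#' construction, since targets sit in positions 3/4 and the singleton
#' is adjacent to the target. Each trial draws its fundamental
#' frequency from a uniform jitter of total width `f0_jitter_hz`
#' around the nominal fundamental.
#'
#' @param config An [experiment_config()].
#' @param seed Integer seed; the same config and seed reproduce the
#'   identical plan.
#' @return A tibble of class `singleton_plan`, one row per trial, with
#'   the seed and config stored as attributes.
#' @export
#' @examples
#' plan <- generate_plan(experiment_config("exp1"), seed = 1)
#' nrow(plan)  # 360
generate_plan <- function(config, seed) {
  stopifnot(inherits(config, "experiment_config"))
  bs <- config$block_size
  nv <- nrow(config$variants)
  n_sing <- bs * config$singleton_share
  n_per_variant <- n_sing / nv
  n_none <- bs - n_sing
  if (n_per_variant != round(n_per_variant) || n_none != round(n_none)) {
    stop(sprintf(
      "block size %d is not divisible into %d singleton variants at share %.2f plus a no-singleton cell",
      bs, nv, config$singleton_share
    ))
  }
  if (n_per_variant %% 2 != 0) {
    stop(sprintf(
      "each variant needs an even per-block count for the before/after split; got %d",
      n_per_variant
    ))
  }
  if (bs %% 4 != 0) {
    stop("block size must be divisible by 4 (target kind x target position)")
  }

  none_row <- tibble::tibble(condition = "none", sc_hz = NA_real_,
                             sc_jnd = 0, am_depth = 0, depth_jnd = 0)
  base <- dplyr::bind_rows(
    none_row[rep(1, n_none), ],
    config$variants[rep(seq_len(nv), each = n_per_variant), ]
  )
  base$singleton_pos <- NA_character_
  is_sing <- base$condition != "none"
  base$singleton_pos[is_sing] <-
    rep(rep(c("before", "after"), each = n_per_variant / 2), nv)
  # cycle target kind x position over the block: exact 50/50 marginals
  combos <- expand.grid(target_kind = c("short", "long"),
                        target_pos = c(3L, 4L),
                        stringsAsFactors = FALSE)
  idx <- rep_len(seq_len(4), bs)
  base$target_kind <- combos$target_kind[idx]
  base$target_pos <- combos$target_pos[idx]

  plan <- withr::with_seed(seed, {
    blocks <- lapply(seq_len(config$n_blocks), function(b) {
      blk <- base[sample.int(bs), ]
      blk$block <- b
      blk$trial <- seq_len(bs)
      blk$f0_hz <- config$f0_nominal_hz +
        runif(bs, -config$f0_jitter_hz / 2, config$f0_jitter_hz / 2)
      blk
    })
    dplyr::bind_rows(blocks)
  })
  plan$experiment <- config$experiment
  plan$singleton_slot <- ifelse(
    is.na(plan$singleton_pos), NA_integer_,
    plan$target_pos + ifelse(plan$singleton_pos == "before", -1L, 1L)
  )
  plan$jnd_total <- abs(plan$sc_jnd) + abs(plan$depth_jnd)
  plan <- plan[, c("experiment", "block", "trial", "condition",
                   "target_kind", "target_pos", "singleton_pos",
                   "singleton_slot", "sc_hz", "sc_jnd", "am_depth",
                   "depth_jnd", "jnd_total", "f0_hz")]
  structure(tibble::as_tibble(plan), class = c("singleton_plan",
                                               class(tibble::tibble())),
            seed = seed, config = config)
}

#' Resolve one planned trial into its five tone specifications
#'
#' Distractors are 170 ms tones at the design's base centroid; the
#' target shares the distractor timbre but lasts 120 ms (short) or
#' 220 ms (long); the singleton, when present, replaces the distractor
#' just before or after the target, with its slope exponent inverted
#' from the trial's centroid value at the trial's jittered fundamental
#' and/or its amplitude-modulation depth set.
#'
#' @param trial A single-row slice of a [generate_plan()] table (or any
#'   list with the same fields).
#' @param config The matching [experiment_config()].
#' @return A list of five [tone_spec()]s, slots 1-5.
#' @export
resolve_trial_tones <- function(trial, config) {
  stopifnot(inherits(config, "experiment_config"))
  f0 <- trial$f0_hz
  lv <- config$levels_db
  alpha_base <- solve_alpha_for_sc(config$base_sc_hz, f0,
                                   config$n_harmonics)
  distractor <- tone_spec(
    f0, alpha_base, config$n_harmonics, config$distractor_ms,
    config$ramp_ms, am_freq_hz = config$am_freq_hz,
    level_db = unname(lv["distractor"])
  )
  target_ms <- if (trial$target_kind == "short") config$target_short_ms
               else config$target_long_ms
  target <- tone_spec(
    f0, alpha_base, config$n_harmonics, target_ms, config$ramp_ms,
    am_freq_hz = config$am_freq_hz,
    level_db = unname(lv[paste0("target_", trial$target_kind)])
  )
  tones <- rep(list(distractor), 5)
  tones[[trial$target_pos]] <- target
  if (!is.na(trial$condition) && trial$condition != "none") {
    alpha_s <- if (!is.na(trial$sc_hz)) {
      solve_alpha_for_sc(trial$sc_hz, f0, config$n_harmonics)
    } else {
      alpha_base
    }
    lvl <- if (trial$condition %in% names(lv)) unname(lv[trial$condition])
           else NA_real_
    tones[[trial$singleton_slot]] <- tone_spec(
      f0, alpha_s, config$n_harmonics, config$distractor_ms,
      config$ramp_ms, am_depth = trial$am_depth,
      am_freq_hz = config$am_freq_hz, level_db = lvl
    )
  }
  tones
}

#' Synthesize the audio of one planned trial
#'
#' @inheritParams resolve_trial_tones
#' @param rate Sampling rate in Hz; defaults to the config's.
#' @return An [audio_buffer()] with the assembled five-tone sequence.
#' @export
synth_trial_sequence <- function(trial, config, rate = config$rate) {
  tones <- resolve_trial_tones(trial, config)
  assemble_sequence(lapply(tones, synth_tone, rate = rate),
                    ioi_ms = config$ioi_ms)
}

#' Tone bank for an experiment at the nominal fundamental
#'
#' Enumerates the distinct tones a design uses (distractor, short and
#' long targets, and each singleton variant) at the nominal,
#' unjittered fundamental, with their slope exponents and closed-form
#' centroids.
#'
#' @param config An [experiment_config()].
#' @return A tibble manifest with one row per tone; the `spec` list
#'   column holds the [tone_spec()]s.
#' @export
build_tone_bank <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  f0 <- config$f0_nominal_hz
  mk <- function(id, sc, depth, dur, level) {
    alpha <- solve_alpha_for_sc(sc, f0, config$n_harmonics)
    tibble::tibble(
      id = id, f0_hz = f0, alpha = alpha, sc_hz = sc, am_depth = depth,
      duration_ms = dur, level_db = level,
      spec = list(tone_spec(f0, alpha, config$n_harmonics, dur,
                            config$ramp_ms, am_depth = depth,
                            am_freq_hz = config$am_freq_hz,
                            level_db = level))
    )
  }
  lv <- config$levels_db
  lvl <- function(id) if (id %in% names(lv)) unname(lv[id]) else NA_real_
  rows <- list(
    mk("distractor", config$base_sc_hz, 0, config$distractor_ms,
       lvl("distractor")),
    mk("target_short", config$base_sc_hz, 0, config$target_short_ms,
       lvl("target_short")),
    mk("target_long", config$base_sc_hz, 0, config$target_long_ms,
       lvl("target_long"))
  )
  for (i in seq_len(nrow(config$variants))) {
    v <- config$variants[i, ]
    sc <- if (is.na(v$sc_hz)) config$base_sc_hz else v$sc_hz
    rows <- c(rows, list(mk(v$condition, sc, v$am_depth,
                            config$distractor_ms, lvl(v$condition))))
  }
  dplyr::bind_rows(rows)
}

#' Write a tone bank to disk
#'
#' Writes `manifest.csv` (tone id, fundamental, exponent, centroid,
#' modulation depth, duration, level) and, optionally, one mono 16-bit
#' WAV per tone.
#'
#' @param bank Output of [build_tone_bank()].
#' @param dir Output directory (created if needed).
#' @param rate Sampling rate for the audio.
#' @param write_audio Write the WAV files (default TRUE).
#' @return The manifest tibble, invisibly.
#' @export
write_tone_bank <- function(bank, dir, rate = 44100, write_audio = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- bank[, setdiff(names(bank), "spec")]
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  if (write_audio) {
    for (i in seq_len(nrow(bank))) {
      write_wav(synth_tone(bank$spec[[i]], rate = rate),
                file.path(dir, paste0(bank$id[i], ".wav")))
    }
  }
  invisible(manifest)
}
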