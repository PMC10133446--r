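test_that("closed-form spectral centroid matches direct summation and limits", {
  # direct-summation oracle
  expect_equal(spectral_centroid(2, 100), sc_by_summation(2, 100))
  expect_equal(spectral_centroid(2, 100), 225.3992, tolerance = 1e-6)
  # steep slope leaves only the fundamental; flat slope averages 1..20
  expect_equal(spectral_centroid(100, 440), 440)
  expect_equal(spectral_centroid(0, 100), 1050)
  # strictly decreasing in alpha
  grid <- spectral_centroid(seq(0, 10, by = 0.25), 385.2)
  expect_true(all(diff(grid) < 0))
})

test_that("centroid inversion is exact and round-trips", {
  f0 <- 512 / sc_by_summation(3, 1)
  for (s in c(538, 563, 640, 768)) {
    a <- solve_alpha_for_sc(s, f0)
    expect_lt(abs(spectral_centroid(a, f0) - s) / s, 1e-6)
  }
  # inverse of the forward map over the exponent range
  for (a in seq(0, 10, by = 1)) {
    s <- spectral_centroid(a, f0)
    expect_equal(solve_alpha_for_sc(s, f0), a, tolerance = 1e-6)
  }
  # the flat-spectrum case has a closed form
  expect_equal(solve_alpha_for_sc(10.5 * 100, 100), 0, tolerance = 1e-6)
  expect_error(solve_alpha_for_sc(90, 100), "not attainable")
  expect_error(solve_alpha_for_sc(5000, 100), "not attainable")
})

test_that("synthesized tones have the centroid the formula predicts", {
  f0 <- 512 / sc_by_summation(3, 1)
  for (alpha in c(0, 1, 2, 3)) {
    b <- synth_tone(tone_spec(f0, alpha))
    expect_equal(measured_sc(b), sc_by_summation(alpha, f0),
                 tolerance = 0.02)
  }
  # a very steep slope is a pure tone at the fundamental
  b <- synth_tone(tone_spec(100, 50))
  expect_equal(measured_sc(b), 100, tolerance = 0.01)
  # pure sinusoid measured within one FFT bin
  n <- round(0.5 * 44100)
  sine <- audio_buffer(sin(2 * pi * 440 * (0:(n - 1)) / 44100), 44100)
  expect_equal(measured_sc(sine, skip_ms = 0), 440,
               tolerance = 44100 / n / 440)
  expect_error(measured_sc(audio_buffer(numeric(1000), 44100)),
               "silence")
})

test_that("synthesis respects Nyquist handling and normalization", {
  spec <- tone_spec(5000, 0.5, n_harmonics = 10)
  expect_error(synth_tone(spec, rate = 44100, strict_nyquist = TRUE),
               "harmonic 5")
  b <- synth_tone(spec, rate = 44100)  # silently drops harmonics >= 22050
  expect_lte(max(abs(b$samples)), 1)
  expect_equal(max(abs(b$samples)), 1)
  expect_equal(length(b$samples), round(0.170 * 44100))
})

test_that("amplitude modulation behaves as specified", {
  b <- synth_tone(tone_spec(385.2, 3, duration_ms = 500))
  expect_identical(apply_am(b, 0), b)
  # unit-depth modulation of a constant spans [0, 2] pre-normalization
  const <- audio_buffer(rep(1, 44100), 44100)
  mod <- apply_am(const, 1, fmod = 50, renormalize = FALSE)
  expect_equal(max(mod$samples), 2, tolerance = 1e-6)
  expect_equal(min(mod$samples), 0, tolerance = 1e-6)
  # demodulated depth recovers the programmed depth
  carrier <- tone_spec(512, 50, duration_ms = 500, ramp_ms = 0)
  for (m in c(0.1, 0.2, 0.5, 1.0)) {
    mb <- apply_am(synth_tone(carrier), m)
    expect_equal(measured_am_depth(mb), m, tolerance = 0.02)
  }
  expect_error(apply_am(b, 1.5), "\\[0, 1\\]")
  # the synthesis path and post-hoc modulation agree
  direct <- synth_tone(tone_spec(512, 50, duration_ms = 500, ramp_ms = 0,
                                 am_depth = 0.5))
  post <- apply_am(synth_tone(carrier), 0.5)
  expect_equal(direct$samples, post$samples, tolerance = 1e-10)
})

test_that("onset and offset ramps are monotone envelopes from and to zero", {
  b <- synth_tone(tone_spec(385.2, 3))
  nr <- round(0.005 * b$rate)
  x <- b$samples
  n <- length(x)
  # the amplitude never exceeds the linear ramp line at either end
  expect_true(all(abs(x[1:nr]) <= (1:nr) / nr + 1e-9))
  expect_true(all(abs(x[n - nr + 1:nr]) <= rev((1:nr)) / nr + 1e-9))
  # and grows/decays across carrier-period chunks within the ramp
  half <- floor(nr / 2)
  expect_lt(max(abs(x[1:half])), max(abs(x[(half + 1):nr])))
  expect_gt(max(abs(x[n - nr + (1:half)])),
            max(abs(x[(n - half + 1):n])))
  expect_lt(abs(x[1]), 0.05)
  expect_lt(abs(x[n]), 0.05)
})

test_that("sequence assembly places tones on the inter-onset grid", {
  rate <- 44100
  tones <- replicate(5, synth_tone(tone_spec(385.2, 3), rate),
                     simplify = FALSE)
  seq5 <- assemble_sequence(tones, ioi_ms = 230)
  expect_equal(length(seq5$samples), round(0.920 * rate) +
                 length(tones[[5]]$samples))
  expect_equal(1000 * length(seq5$samples) / rate, 1090, tolerance = 1e-3)
  # a 220 ms tone in slot 4 leaves energy beyond 910 ms
  tones[[4]] <- synth_tone(tone_spec(385.2, 3, duration_ms = 220), rate)
  mixed <- assemble_sequence(tones, ioi_ms = 230)
  win <- (round(0.900 * rate)):(round(0.908 * rate))
  expect_gt(max(abs(mixed$samples[win])), 0)
  # energies add when tones do not overlap
  short <- replicate(5, synth_tone(tone_spec(385.2, 3, duration_ms = 100),
                                   rate), simplify = FALSE)
  total <- assemble_sequence(short, ioi_ms = 230)
  expect_equal(sum(total$samples^2),
               sum(vapply(short, function(b) sum(b$samples^2), numeric(1))),
               tolerance = 1e-10)
})

test_that("WAV output round-trips through the PCM16 reader", {
  b <- synth_tone(tone_spec(385.2, 3), rate = 8000)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(b, path)
  back <- read_wav(path)
  expect_equal(back$rate, 8000)
  expect_equal(back$samples, b$samples, tolerance = 1 / 32767 * 2)
  expect_identical(file.size(path), 44 + 2 * length(b$samples))
})
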