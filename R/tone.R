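#' Parametric description of one harmonic complex tone
#'
#' A tone is a sum of `n_harmonics` harmonics of a fundamental `f0`, the
#' n-th harmonic having frequency `n * f0` and amplitude `1 / n^alpha`.
#' Larger `alpha` concentrates energy in the fundamental (darker timbre,
#' lower spectral centroid); `alpha = 0` weighs all harmonics equally.
#' Roughness is parameterized by sinusoidal amplitude modulation of depth
#' `am_depth` at `am_freq_hz` (50 Hz by default, the range perceived as
#' rough rather than as beating or as separate events).
#'
#' @param f0 Fundamental frequency in Hz (> 0).
#' @param alpha Spectral slope exponent (dimensionless, finite).
#' @param n_harmonics Number of harmonics (default 20).
#' @param duration_ms Total duration in ms.
#' @param ramp_ms Linear onset/offset ramp in ms (default 5); the two
#'   ramps must fit inside the duration.
#' @param am_depth Amplitude-modulation depth m in `[0, 1]` (0 = none).
#' @param am_freq_hz Modulation frequency in Hz (default 50).
#' @param level_db Nominal presentation level in dB SPL. Metadata only:
#'   synthesis always peak-normalizes, levels are carried for manifests.
#'
#' @return An object of class `tone_spec`.
#' @export
#' @examples
#' tone_spec(f0 = 385.2, alpha = 3)
tone_spec <- function(f0, alpha, n_harmonics = 20L, duration_ms = 170,
                      ramp_ms = 5, am_depth = 0, am_freq_hz = 50,
                      level_db = NA_real_) {
  stopifnot(is.numeric(f0), length(f0) == 1L, f0 > 0)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  stopifnot(n_harmonics >= 1L)
  stopifnot(duration_ms > 0, ramp_ms >= 0, 2 * ramp_ms <= duration_ms)
  if (am_depth < 0 || am_depth > 1) {
    stop("`am_depth` must lie in [0, 1], got ", am_depth)
  }
  structure(
    list(
      f0 = f0, alpha = alpha, n_harmonics = as.integer(n_harmonics),
      duration_ms = duration_ms, ramp_ms = ramp_ms,
      am_depth = am_depth, am_freq_hz = am_freq_hz, level_db = level_db
    ),
    class = "tone_spec"
  )
}

#' @export
print.tone_spec <- function(x, ...) {
  cat(sprintf(
    "<tone_spec> f0 = %.1f Hz, alpha = %.3f (SC = %.1f Hz), %g ms, AM depth %.2f\n",
    x$f0, x$alpha, spectral_centroid(x$alpha, x$f0, x$n_harmonics),
    x$duration_ms, x$am_depth
  ))
  invisible(x)
}

#' Audio sample buffer
#'
#' Peak-normalized mono audio: `abs(samples) <= 1`.
#'
#' @param samples Numeric vector of amplitudes.
#' @param rate Sampling rate in Hz.
#' @return An object of class `audio_buffer`.
#' @export
audio_buffer <- function(samples, rate) {
  stopifnot(is.numeric(samples), rate > 0)
  if (length(samples) && max(abs(samples)) > 1 + 1e-9) {
    stop("audio_buffer samples must be peak-normalized (|x| <= 1)")
  }
  structure(list(samples = as.numeric(samples), rate = rate),
            class = "audio_buffer")
}

#' @export
print.audio_buffer <- function(x, ...) {
  cat(sprintf("<audio_buffer> %d samples @ %g Hz (%.1f ms)\n",
              length(x$samples), x$rate, 1000 * length(x$samples) / x$rate))
  invisible(x)
}

#' Closed-form spectral centroid of a harmonic complex
#'
#' For harmonics `i = 1..N` at frequencies `i * f0` with amplitudes
#' `1 / i^alpha`, the amplitude-weighted mean frequency is
#' `f0 * sum(i^(1 - alpha)) / sum(i^(-alpha))`. Strictly decreasing in
#' `alpha` for `N >= 2`; tends to `f0` as `alpha -> Inf` and to
#' `f0 * (N + 1) / 2` at `alpha = 0`.
#'
#' @param alpha Spectral slope exponent(s); vectorized.
#' @param f0 Fundamental frequency in Hz.
#' @param n_harmonics Number of harmonics.
#' @return Spectral centroid(s) in Hz.
#' @export
#' @examples
#' spectral_centroid(2, 100)    # 225.40 Hz
#' spectral_centroid(0, 100)    # 1050 Hz: mean of harmonics 1..20
spectral_centroid <- function(alpha, f0, n_harmonics = 20L) {
  stopifnot(n_harmonics >= 1L)
  i <- seq_len(n_harmonics)
  vapply(alpha, function(a) f0 * sum(i^(1 - a)) / sum(i^(-a)), numeric(1))
}

#' Invert the spectral centroid for the slope exponent
#'
#' Finds `alpha` such that the closed-form spectral centroid equals
#' `target_sc`. The centroid is strictly monotone decreasing in `alpha`,
#' so the root is unique within the search range.
#'
#' @param target_sc Desired spectral centroid in Hz. Must lie strictly
#'   above `f0` and at or below the centroid at `alpha_range[1]`.
#' @param f0 Fundamental frequency in Hz.
#' @param n_harmonics Number of harmonics.
#' @param alpha_range Search interval for the exponent.
#' @param tol Relative tolerance on the achieved centroid.
#' @return The slope exponent `alpha`.
#' @export
#' @examples
#' solve_alpha_for_sc(512, f0 = 385.2014)  # ~3
solve_alpha_for_sc <- function(target_sc, f0, n_harmonics = 20L,
                               alpha_range = c(0, 100), tol = 1e-9) {
  sc_max <- spectral_centroid(alpha_range[1], f0, n_harmonics)
  sc_min <- spectral_centroid(alpha_range[2], f0, n_harmonics)
  if (target_sc <= sc_min || target_sc > sc_max) {
    stop(sprintf(
      "target SC %.2f Hz not attainable: reachable interval is (%.2f, %.2f] Hz for alpha in [%g, %g]",
      target_sc, sc_min, sc_max, alpha_range[2], alpha_range[1]
    ))
  }
  root <- uniroot(
    function(a) spectral_centroid(a, f0, n_harmonics) - target_sc,
    interval = alpha_range, tol = .Machine$double.eps^0.75
  )
  alpha <- root$root
  achieved <- spectral_centroid(alpha, f0, n_harmonics)
  if (abs(achieved - target_sc) / target_sc > tol) {
    stop("centroid inversion did not converge to requested tolerance")
  }
  alpha
}

linear_ramp <- function(n_samples, ramp_ms, rate) {
  env <- rep(1, n_samples)
  nr <- round(ramp_ms / 1000 * rate)
  if (nr > 0) {
    up <- seq(0, 1, length.out = nr + 1L)[-1L]
    env[seq_len(nr)] <- up
    env[n_samples - nr + seq_len(nr)] <- rev(up)
  }
  env
}

#' Synthesize a harmonic complex tone
#'
#' Sums sine-phase harmonics `sin(2 pi n f0 t) / n^alpha`, applies
#' amplitude modulation when `am_depth > 0`, applies the linear
#' onset/offset ramps, and peak-normalizes. Harmonics at or above the
#' Nyquist frequency are silently dropped unless `strict_nyquist`.
#'
#' @param spec A [tone_spec()].
#' @param rate Sampling rate in Hz (default 44100).
#' @param strict_nyquist Error (naming the harmonic) instead of dropping
#'   harmonics above Nyquist.
#' @return An [audio_buffer()].
#' @export
synth_tone <- function(spec, rate = 44100, strict_nyquist = FALSE) {
  stopifnot(inherits(spec, "tone_spec"))
  n <- round(spec$duration_ms / 1000 * rate)
  t <- (seq_len(n) - 1) / rate
  harm <- seq_len(spec$n_harmonics)
  freqs <- harm * spec$f0
  keep <- freqs < rate / 2
  if (!all(keep) && strict_nyquist) {
    stop(sprintf("harmonic %d (%.0f Hz) is at or above Nyquist (%.0f Hz)",
                 which(!keep)[1], freqs[!keep][1], rate / 2))
  }
  harm <- harm[keep]
  w <- harm^(-spec$alpha)
  x <- as.numeric(sin(outer(t, 2 * pi * spec$f0 * harm)) %*% w)
  if (spec$am_depth > 0) {
    x <- x * (1 + spec$am_depth * cos(2 * pi * spec$am_freq_hz * t))
  }
  x <- x * linear_ramp(n, spec$ramp_ms, rate)
  audio_buffer(x / max(abs(x)), rate)
}

#' Apply sinusoidal amplitude modulation
#'
#' Multiplies the signal by `1 + m * cos(2 pi fmod t)` and, by default,
#' re-peak-normalizes so the nominal level does not depend on the
#' modulation envelope (presentation levels are handled as metadata
#' after loudness equalization, not in synthesis).
#'
#' @param buffer An [audio_buffer()].
#' @param m Modulation depth in `[0, 1]`.
#' @param fmod Modulation frequency in Hz.
#' @param renormalize Re-peak-normalize after modulation (default TRUE).
#' @return The modulated [audio_buffer()].
#' @export
apply_am <- function(buffer, m, fmod = 50, renormalize = TRUE) {
  stopifnot(inherits(buffer, "audio_buffer"))
  if (m < 0 || m > 1) stop("modulation depth `m` must lie in [0, 1]")
  if (m == 0) return(buffer)
  t <- (seq_along(buffer$samples) - 1) / buffer$rate
  x <- buffer$samples * (1 + m * cos(2 * pi * fmod * t))
  if (renormalize) x <- x / max(abs(x))
  structure(list(samples = x, rate = buffer$rate), class = "audio_buffer")
}

#' Measure the spectral centroid of an audio buffer
#'
#' Amplitude-spectrum-weighted mean frequency of the steady-state
#' segment (ramps excluded), Hann-windowed. Serves as the spectral
#' oracle against the closed-form [spectral_centroid()].
#'
#' @param buffer An [audio_buffer()].
#' @param skip_ms Segment dropped at each end before the transform
#'   (default 10 ms, generously covering the 5 ms ramps).
#' @return Measured centroid in Hz.
#' @export
measured_sc <- function(buffer, skip_ms = 10) {
  stopifnot(inherits(buffer, "audio_buffer"))
  x <- buffer$samples
  ns <- round(skip_ms / 1000 * buffer$rate)
  if (length(x) > 2 * ns + 16) x <- x[(ns + 1):(length(x) - ns)]
  if (all(x == 0)) stop("cannot measure the spectral centroid of silence")
  n <- length(x)
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  amp <- Mod(fft(x * hann))[seq_len(floor(n / 2))]
  freq <- (seq_len(floor(n / 2)) - 1) * buffer$rate / n
  sum(freq * amp) / sum(amp)
}

#' Concatenate tones into a five-tone trial sequence
#'
#' Tone k starts at `(k - 1) * ioi_ms`; overlapping tails are summed.
#' The buffer length is `(k - 1) * ioi_ms` plus the last tone's
#' duration. With the default 230 ms inter-onset interval and tone
#' durations up to 220 ms, tones never overlap; should summation ever
#' exceed full scale the buffer is scaled back to peak 1.
#'
#' @param tones List of [audio_buffer()]s (normally 5), equal rates.
#' @param ioi_ms Inter-onset interval in ms (default 230).
#' @return The assembled [audio_buffer()].
#' @export
assemble_sequence <- function(tones, ioi_ms = 230) {
  stopifnot(length(tones) >= 1,
            all(vapply(tones, inherits, logical(1), "audio_buffer")))
  rate <- tones[[1]]$rate
  stopifnot(all(vapply(tones, function(b) b$rate, numeric(1)) == rate))
  onsets <- round((seq_along(tones) - 1) * ioi_ms / 1000 * rate)
  total <- max(onsets + vapply(tones, function(b) length(b$samples),
                               integer(1)))
  out <- numeric(total)
  for (k in seq_along(tones)) {
    idx <- onsets[k] + seq_along(tones[[k]]$samples)
    out[idx] <- out[idx] + tones[[k]]$samples
  }
  peak <- max(abs(out))
  if (peak > 1) out <- out / peak
  audio_buffer(out, rate)
}

#' Write / read mono 16-bit PCM WAV
#'
#' Minimal canonical RIFF/WAVE I/O for the synthesized stimuli. Samples
#' are scaled by 32767 and rounded.
#'
#' @param buffer An [audio_buffer()].
#' @param path Output file path.
#' @return `write_wav()` returns `path` invisibly; `read_wav()` returns
#'   an [audio_buffer()].
#' @export
write_wav <- function(buffer, path) {
  stopifnot(inherits(buffer, "audio_buffer"))
  pcm <- as.integer(round(pmax(-1, pmin(1, buffer$samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(buffer$rate), con, size = 4, endian = "little")
  writeBin(as.integer(buffer$rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (riff != "RIFF" || wave != "WAVE") stop("not a RIFF/WAVE file: ", path)
  rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk in ", path)
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) stop("only mono PCM supported")
      rate <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, raw(), n = sz - 8L)
    } else if (id == "data") {
      pcm <- readBin(con, integer(), n = sz / 2L, size = 2,
                     endian = "little")
      return(audio_buffer(pcm / 32767, rate))
    } else {
      readBin(con, raw(), n = sz)
    }
  }
}
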