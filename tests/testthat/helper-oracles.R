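# Independent oracles, kept free of the package's own code paths.

# Spectral centroid by direct summation of the harmonic series.
sc_by_summation <- function(alpha, f0, n = 20) {
  i <- seq_len(n)
  f0 * sum(i * i^(-alpha)) / sum(i^(-alpha))
}

# Envelope by FFT-based analytic signal (Hilbert transform).
envelope_hilbert <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(fft(x) * h, inverse = TRUE) / n)
}

# Demodulated AM depth: (max - min) / (max + min) of the envelope over
# whole modulation cycles in the steady-state segment.
measured_am_depth <- function(buffer, fmod = 50, skip_ms = 20) {
  ns <- round(skip_ms / 1000 * buffer$rate)
  x <- buffer$samples[(ns + 1):(length(buffer$samples) - ns)]
  env <- envelope_hilbert(x)
  # trim the transform's edge artifacts
  cut <- round(length(env) * 0.1)
  env <- env[(cut + 1):(length(env) - cut)]
  (max(env) - min(env)) / (max(env) + min(env))
}

# A small trial-record table with known structure, for analysis tests.
make_records <- function(participant, condition, rt_ms,
                         correct = TRUE, response = "short",
                         target_kind = "short",
                         sc_jnd = 0, depth_jnd = 0) {
  tibble::tibble(
    participant = participant, condition = condition,
    target_kind = target_kind, response = response,
    correct = correct, rt_ms = rt_ms,
    sc_jnd = sc_jnd, depth_jnd = depth_jnd,
    jnd_total = abs(sc_jnd) + abs(depth_jnd)
  )
}
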