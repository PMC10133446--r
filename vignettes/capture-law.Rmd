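---
title: "The linear capture law: models, design choices and numerical details"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The linear capture law: models, design choices and numerical details}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(singletone)
```

## The paradigm and the model

Listeners hear sequences of five harmonic tones at a constant 230 ms
inter-onset interval and report whether the target — the one tone that
is 50 ms shorter (120 ms) or longer (220 ms) than the 170 ms
distractors — is "short" or "long". The target occupies position 3 or
4; the first tone is always a distractor, so the sequence establishes
the reference duration before anything can deviate. On singleton
trials one distractor adjacent to the target (just before or just
after, 50/50) differs in timbre: a different spectral centroid
(brightness), a 50 Hz amplitude modulation (roughness), or both.

The package's central object is the **capture law**. A singleton whose
features deviate from the distractors by $\Delta_b$ brightness jnd and
$\Delta_r$ roughness jnd adds an expected cost to the reaction time:

$$\Delta RT = s_b\,|\Delta_b| + s_r\,|\Delta_r|$$

with per-feature slopes $s_b, s_r$ in ms/jnd. Three structural
assumptions are built in, each testable by one of the packaged
designs: *linearity* in the deviation (the graded ladders of `exp2`
and `exp3`), *sign symmetry* — a duller singleton costs the same as an
equally deviant brighter one (`exp4`, deviations of ±2 and ±4 jnd from
a 631 Hz distractor), and *additivity* across features (`exp5`,
brightness and roughness combined at summed deviations of 4, 7, 7 and
10 jnd). The perceptual units are a 5% relative jnd on the spectral
centroid and a 10% jnd on the modulation-depth scale.

## Stimuli

Tones have 20 harmonics with weights $1/n^\alpha$, all in sine phase
(the phase is perceptually irrelevant for these stimuli and a fixed
choice keeps synthesis deterministic). The closed-form centroid
$SC(\alpha) = f_0 \sum i^{1-\alpha} / \sum i^{-\alpha}$ is strictly
decreasing in $\alpha$, so any target centroid in the attainable range
$(f_0,\ 10.5 f_0]$ has a unique exponent, found by `uniroot` to
machine precision and verified to $10^{-6}$ relative tolerance.

Two numerical choices deserve note:

* **The fundamental is not a free parameter of the designs.** It is
  derived once from the anchor "α = 3 gives a 512 Hz centroid", i.e.
  $f_0 \approx 385.2$ Hz. The alternative anchor "α = 2 gives 822 Hz"
  is *inconsistent* with the first at any single $f_0$ (the formula
  gives a 822/512 ratio of 1.70 where these values imply 1.61), so the
  package treats published centroid values as authoritative and always
  obtains exponents by inversion, never by fixing α = 2. The bright
  `exp1` singleton is therefore the tone whose centroid is 822 Hz.
* **Per-trial fundamental jitter.** Each trial's $f_0$ is drawn
  uniformly from a 20 Hz-wide band centred on the nominal value, an
  interpretation of "a broad uniform distribution of 20 Hz" that we
  read as total width; it is configurable (`f0_jitter_hz`), and the
  singleton's exponent is re-inverted at the jittered fundamental so
  its centroid deviation is preserved exactly.

Amplitude modulation multiplies the waveform by
$1 + m\cos(2\pi \cdot 50 t)$. Synthesis re-peak-normalizes after
modulation and ramping: presentation levels were equalized in loudness
experimentally, so the package carries the equalized dB SPL values as
metadata in configs and manifests rather than modelling loudness.
Ramps are linear, 5 ms. Harmonics at or above Nyquist are dropped
silently by default (at $f_0 \approx 385$ Hz the 20th harmonic is
~7.7 kHz, far below Nyquist at the default 44.1 kHz rate); a strict
mode errors instead, naming the offending harmonic.

`exp4`'s published centroids (512, 569, 696, 768 Hz) are carried
verbatim as a literal ladder: 696 Hz is exactly 2 compound jnd above
631 Hz, but no single additive or compound rule reproduces all four
printed values, and stimulus values take precedence over any
generating rule. `exp2` uses additive steps
($512(1 + 0.05k)$) and `exp5` compound steps ($512 \cdot 1.05^k$) —
in each case the rule that reproduces that design's printed values.

## Trial plans

Blocks are balanced exactly, not in expectation: per block, short/long
targets 50/50, positions 3/4 50/50, singleton conditions at their
configured shares (50% present for `exp1`; 20% per variant plus 20%
absent for the four-variant designs), and before/after placement 50/50
within every variant. For `exp1`, 30 singleton-absent trials cannot be
spread evenly over the four kind-by-position cells, so joint balance
is approximate there while all marginal constraints remain exact (a
cyclic assignment of the four kind-by-position combinations guarantees
this); for the 80-trial blocks every variant count (16) is divisible
by every cell count, and the balance is fully factorial. Block counts
for `exp4` and `exp5` are not stated in the source design; they reuse
the 8 × 80 structure of the other four-variant designs. Plans are
deterministic given a seed.

## The generative observer

Per trial: $RT = \mu + \Delta RT + \varepsilon$, with
$\varepsilon \sim N(0, \sigma^2)$ truncated below at 0; draws at or
past the 3000 ms deadline become missing responses. The deadline and
the reaction time are both referenced to target onset (the measurement
origin of the paradigm; where the deadline's clock origin is ambiguous
we use target onset). Errors occur with probability
$p_e = p_0 + g \cdot (|\Delta_b| + |\Delta_r|)$, clipped to $[0,1]$ —
errors tracking the RT cost is itself a reported regularity of the
paradigm. With probability `lapse_rate` the response is random and the
reaction time uniform over the response window, which generates the
anticipations (< 100 ms) and deadline misses the cleaning rules exist
to remove. A truncated normal is the default noise model because only
means and SDs of the cohorts are available to constrain it; nothing in
the pipeline depends on the shape beyond its first two moments.

Defaults are anchored to the published `exp1` cohort: baseline
$\mu$ = 985 ms with a 140 ms between-participant SD, within-trial
$\sigma$ = 150 ms, slopes 14.0 and 12.4 ms/jnd, baseline error rate
0.162, and error gain $g = 0.0066$/jnd — the value that reproduces the
published 16.2% vs 24.2% error rates at the bright singleton's
ladder-equivalent deviation of $(822/512 - 1)/0.05 \approx 12.1$ jnd.
A position term (singleton-after costlier than singleton-before) is
supported but defaults to 0, since its published magnitude is unknown;
no trial-history effects are modelled, consistent with the null
surprise effect the paradigm reports.

What the generator does *not* emulate: sequential dependencies
(practice, fatigue, post-error slowing), heavy-tailed RT distributions,
fast guesses correlated with accuracy, or any top-down modulation of
capture. Recovery tests passing on this generator therefore show that
the *pipeline* is unbiased under the stated law — not that human data
obey the law.

## Analysis pipeline

Participants with error rates of 40% or more are excluded (the rule
keeps rates strictly *below* 40%). Cleaning then removes no-answer
trials, reaction times under 100 ms, and — per participant by
singleton condition (each variant is its own cell) — trials more than
2 sample SDs from the cell mean, in one pass. Cells under 3 trials
pass through untrimmed with a warning, as a two-point SD is
uninformative. Note a small-sample fact worth knowing: in a cell of
$n$ trials no point can lie beyond $(n-1)/\sqrt{n}$ sample SDs, so the
2-SD rule cannot remove anything from cells of 5 or fewer trials; it
only bites at realistic cell sizes.

Reaction-time increases are computed per participant (condition mean
of correct trials minus the same participant's no-singleton mean),
then averaged across participants; condition standard errors are
across participants. The capture-law fit regresses the condition-mean
increases on the total jnd deviation by ordinary least squares and
reports the slope, its standard error and Pearson's r; a constant
response is flagged degenerate with slope 0. LISAS is computed per
participant per condition (mean correct RT plus the error proportion
scaled by the cell's RT-to-error-indicator SD ratio, sample SDs; the
per-cell variant is a choice — the source is silent on pooling — and
is the one consistent with the rest of the per-cell pipeline).

Paired tests default to two-tailed; the power calculation defaults to
one-tailed, mirroring how each is used in the paradigm (the power
analysis that fixes the minimum cohort at $N = 12$ for $d = 0.8$,
$\alpha = 0.05$, power 0.8 is explicitly one-tailed). The
`exp1` singleton is assigned its ladder-equivalent 12.1 jnd when its
point joins a combined capture-law fit; this is bookkeeping only and
configurable.

## Problem sizes and determinism

The recovery analyses packaged in the tests and the acceptance script
use cohorts of 20 participants × 640 trials — the full published
design size of the four-variant experiments — which run in seconds
and give slope standard errors of ~0.2-0.9 ms/jnd, comfortably
resolving the 14.0/12.4/8.5 ms/jnd generating values. Every stochastic
step (plan shuffling, participant parameter draws, trial noise) is
reproducible from a single integer seed; participant streams are
derived from it with a large prime stride.

## Known limitations

* The capture law is linear by construction; it cannot express the
  saturation that must occur at large deviations, and fits should not
  be extrapolated beyond the ~12 jnd range the designs cover.
* Loudness is metadata: the package does not model the masking or
  salience contributions of level, which the experimental procedure
  removed by equalization.
* The observer's error model is a convenience calibrated to two
  published error rates; it is not a process model of duration
  discrimination.
* `position_effect()` and `surprise_effect()` require trial-order
  information; logs lacking a `presentation` column can only support
  the position test.
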