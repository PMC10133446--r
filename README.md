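# singletone

Auditory attentional capture by timbre singletons: stimulus synthesis,
experiment design, observer simulation, and the full reaction-time
analysis pipeline, in one R package.

## The problem

In the auditory additional-singleton paradigm, listeners hear rapid
five-tone sequences and judge whether one tone — the *target* — is
shorter or longer than the others. On most trials one of the
non-target tones, the *singleton*, differs on a task-irrelevant timbre
dimension. Although ignoring it is the optimal strategy, a
sufficiently salient singleton captures attention and slows the
duration judgment. Measuring that cost as the singleton's timbre is
pushed further from the distractors, in perceptual units
(just-noticeable differences, jnd), traces out how stimulus features
drive bottom-up attention.

The package targets two timbre attributes:

* **brightness**, controlled through the spectral centroid (SC) of a
  20-harmonic complex with harmonic weights 1/n^α — the centroid is
  `SC = f0 · Σ i^(1−α) / Σ i^(−α)`, strictly decreasing in α, and the
  package inverts this map so stimuli can be specified directly in Hz;
* **roughness**, controlled through the depth m of 50 Hz sinusoidal
  amplitude modulation, `s(t) = (1 + m·cos(2π·50·t)) · s₀(t)`.

At the core is a linear capture law: the expected reaction-time
increase produced by a singleton deviating by Δb brightness jnd and
Δr roughness jnd is

```
ΔRT = slope_b · |Δb| + slope_r · |Δr|
```

— linear in the perceived deviation, symmetric in sign, and additive
across features. The package simulates observers obeying this law
(plus RT noise, errors, lapses, and a 3000 ms deadline) and recovers
its slopes with the same cleaning and statistics a behavioral study
would use: per-participant 2-SD trimming, <100 ms and no-answer
removal, correct-only RT means, LISAS, paired t-tests with Holm
correction, Cohen's d, noncentral-t power analysis, and ordinary
least squares of RT cost on jnd deviation.

Intended users: auditory-attention and psychophysics researchers who
want a tested reference implementation of the paradigm — for power
planning, analysis-pipeline validation on synthetic data with known
ground truth, or generating the actual stimulus audio.

## Worked example

Simulate the four-level brightness design (8 blocks × 80 trials,
singleton SCs 538/563/640/768 Hz, i.e. 1/2/5/10 jnd above the 512 Hz
distractors) with 20 observers whose generating brightness slope is
14 ms/jnd, then run the analysis:

```r
library(singletone)

sim      <- simulate_experiment("exp2", seed = 1)
analysis <- analyze_experiment(sim$records)
analysis
#> <cleaning_report> 97.0% of 12800 trials kept (78.6% kept and correct)
#>   removed: 0 no-answer, 3 under floor, 376 beyond the SD band
#>
#> Mean RT increase by condition:
#> # A tibble: 4 × 7
#>   condition sc_jnd depth_jnd jnd_total mean_increase_ms se_ms n_participants
#>   <chr>      <dbl>     <dbl>     <dbl>            <dbl> <dbl>          <int>
#> 1 sc538          1         0         1             8.64  5.54             20
#> 2 sc563          2         0         2            24.6   4.25             20
#> 3 sc640          5         0         5            67.0   4.78             20
#> 4 sc768         10         0        10           137.    5.75             20
#>
#> Singleton presence: t(19) = 14.67, p = 8.1e-12, d = 3.28
#>
#> <jnd_regression> slope = 14.13 ms/jnd (se 0.16), intercept -4.4 ms, r = 0.9999, 4 points
```

Reading the output: trimming kept 97% of trials; the per-condition RT
increases grow essentially linearly with the singleton's deviation
(8.6 ms at 1 jnd up to 137 ms at 10 jnd); the presence of any
singleton slows responses massively (d = 3.3); and the fitted capture
law recovers the generating 14 ms/jnd slope within one standard
error.

Other entry points:

```r
# minimum sample size for a one-tailed paired t-test, d = 0.8, power 0.8
power_sample_size(0.8, 0.05, 0.8, "one")   # 12

# the printed stimulus values of the brightness ladder
build_ladder(feature_ladder("brightness_sc", 512, 0.05,
                            c(1, 2, 5, 10), "additive"), rounded = TRUE)
#> [1] 538 563 640 768

# synthesize and write a design's tone bank as WAV + manifest
write_tone_bank(build_tone_bank(experiment_config("exp2")), "audio/")

# full chain with all artifacts (plan, trial log, tests, figures)
reproduce_experiment("exp3", seed = 1, out_dir = "results/exp3")
```

A command-line wrapper for the full chain is
`Rscript scripts/reproduce.R --experiment exp2 --seed 1 --out results/exp2`.

## Package layout

| Module | Contents |
|---|---|
| `R/tone.R` | tone specs, synthesis, SC formula + inversion, AM, sequence assembly, WAV I/O |
| `R/ladder.R` | jnd-scaled feature ladders |
| `R/plan.R` | experiment configurations, balanced trial plans, trial→tone resolution, tone banks |
| `R/observer.R` | capture law, trial/cohort simulation, observer populations |
| `R/clean.R`, `R/stats.R`, `R/summaries.R` | exclusion, trimming, LISAS, paired t/Holm/power, jnd regression, position & surprise tests |
| `R/pipeline.R` | end-to-end drivers, trial-log CSV I/O, figures |

The methods vignette (`vignettes/capture-law.Rmd`) documents the
model, the generative assumptions, and every numerical choice.
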