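# pupilkit

Preprocessing and statistical analysis of task-evoked pupillometry data in
R, for researchers who run trial-based experiments in which the measure of
interest is the pupil response to a stimulus — attention, effort, arousal,
working-memory studies and the like.

The pupil is a continuous, autocorrelated signal: each trial yields not one
dependent variable but hundreds of time samples, which makes naive
per-sample testing a multiple-comparison trap. pupilkit implements the full
workflow around that problem:

* a **trial table**: a tibble with one row per trial in which scalar
  variables (participant, condition, RT) coexist with trials × samples
  matrix columns for pupil and gaze series; parsers build it from an
  EyeLink-style ASCII log or a long one-row-per-sample table;
* **preprocessing** in its mandatory order — velocity-based blink
  reconstruction with cubic-spline interpolation, block-mean downsampling,
  arbitrary-units-to-millimetres calibration (`mm = a·units^b`),
  subtractive or divisive baseline correction, and within-participant
  z-score trial exclusion (|z| > 2);
* **data-quality metrics** mirroring the field's recommended visual checks
  (spike trials, missing data, baseline distributions, blink-rate and gaze
  imbalance by condition), with ggplot2 helpers;
* three **statistical procedures** built on a linear mixed-effects
  contract (Wald z = estimate/SE, two-tailed normal p): a
  predetermined-window test, a cluster-based permutation test with
  within-participant label shuffling, and a deterministic four-fold
  interleaved cross-validation test that localizes each effect's most
  informative sample on training folds and tests held-out trials there;
* a **synthetic-data generator** with known ground truth (response-kernel
  condition effects, participant random effects, slow arousal drift,
  realistic blink morphology), so the whole pipeline is verifiable without
  any external recording.

Per-sample scans inside permutations and localization run on a compiled
profiled-REML random-intercept fitter that matches `lme4` to numerical
precision at a tiny fraction of the cost; final models go through `lme4`.

## A worked example

Simulate a 10-participant experiment (3000 ms epochs at 1000 Hz, three
cue-eccentricity conditions coded −1/0/1), preprocess it, and test the
condition effect:

```r
library(pupilkit)

sim <- simulate_dataset(synthetic_spec(n_participants = 10, seed = 42))
sim$data
#> # A trial table: 390 trials, 10 participant(s)
#> # series `pupil`: 3000 samples @ 1000 Hz, t0 = 0 ms
#> # series `gaze_x`: 3000 samples @ 1000 Hz, t0 = 0 ms
#> # series `gaze_y`: 3000 samples @ 1000 Hz, t0 = 0 ms
#> # A tibble: 390 x 7 ...

clean <- sim$data |>
  pp_reconstruct("pupil") |>   # blinks: detect + spline-interpolate
  pp_downsample(10) |>         # 1000 Hz -> 100 Hz, 300 samples
  pp_baseline(c(0, 50))        # subtract the first-50-ms mean

excl <- exclude_baseline_outliers(clean)
#> excluded 14 of 390 trials (3.59%)
```

A single test on the predetermined 750–3000 ms window:

```r
window_test(excl$data, "pupil", c(750, 3000), "ecc_code",
            random = "intercept")
#> Linear mixed-effects fit (Wald z, normal-approximation p)
#>    .window_mean ~ ecc_code + (1 | participant)
#>   n = 376
#>   term        estimate    se     z           p
#> 1 (Intercept)     1.54  3.37 0.455 0.649
#> 2 ecc_code       14.3   2.79 5.13  0.000000289
```

The per-unit-of-coding effect on mean baseline-corrected pupil size over
the window is ≈ 14 arbitrary units (z = 5.13): pupil size increases with
cue eccentricity. The cross-validation test instead localizes the most
informative sample per fold and tests held-out trials there:

```r
crossval_test(excl$data, "pupil", "ecc_code")
#> Cross-validation test on `pupil` (4-fold interleaved split; final
#> random structure: slopes)
#>   ecc_code: tested at sample(s) 169, 170, 171 (1690, 1700, 1710 ms)
#>   term     estimate    se     z        p n_used n_dropped converged
#> 1 ecc_code     45.6  4.17  10.9 9.04e-28    372         4 TRUE
```

All folds localize the effect around 1700 ms — close to the simulated
response peak (kernel peaking 1000 ms after the 750 ms effect onset) — and
the held-out test recovers a per-coding-unit effect of ≈ 46 units at the
tested samples. `tidy()` and `glance()` methods return these results as
tibbles; `autoplot()` draws the condition-wise trace plot with the
tested-sample marker, and `plot_traces()` / `plot_baseline_hist()` /
`plot_blink_counts()` / `plot_gaze_deviation()` cover the data-quality
views. `run_pipeline()` (or the `inst/cli/pupilkit.R` script) executes the
whole chain from a YAML configuration.

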