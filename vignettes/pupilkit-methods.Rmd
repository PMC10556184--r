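---
title: "Models and methods behind pupilkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pupilkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilkit)
```

pupilkit implements a complete workflow for trial-based cognitive
pupillometry: parsing trial-structured eye-tracker recordings, cleaning the
pupil trace, quantifying data quality, and testing condition effects on the
pupil time series while controlling the multiple-comparison problem that a
continuous dependent variable creates. This vignette explains the models and
the numerical decisions; the README shows a worked example.

## The data model

A `trial_table()` is a tibble with one row per trial. Scalar columns
(participant, condition codes, response time) coexist with *series* columns:
numeric matrices of trials x samples, each carrying a sampling rate and an
epoch-zero time in the table's `series_meta` attribute. This mirrors the
field's convention of epoching a continuous recording around stimulus
events. Three conventions remove all off-by-one ambiguity:

* time is in milliseconds everywhere, sample indices are 0-based, and all
  windows and index ranges are half-open `[start, end)`;
* sample `i` covers `[t0 + i * dt, t0 + (i + 1) * dt)` with
  `dt = 1000 / rate_hz`; `window_to_samples()` returns the indices whose
  coverage intervals overlap a window, so a window narrower than one sample
  still maps to that sample;
* missing data is `NA` and nothing else. Video-based trackers code missing
  pupil size as 0; the parsers recode on ingest, so a literal 0 never
  reaches the analysis layer. Ragged epochs are right-padded with `NA`
  (padding recorded per trial), and every statistic skips missing cells.

## Blink reconstruction

An eyelid closing occludes the pupil within ~10 ms: the recorded size ramps
down sharply, disappears, and ramps back up on reopening. The cleaning
problem is to find these events, interpolate the short ones (where pupil
size is predictable), and discard everything else suspicious.

`reconstruct_blinks()` detects blinks by velocity on a smoothed working
copy (10 ms moving average): a blink starts where velocity falls below the
onset threshold, spans any missing run, and ends where velocity stabilizes
below the offset threshold after the reopening rise. The extent, widened by
a 10 ms margin, is interpolated with a cubic spline through four anchor
points — two before onset and two after offset, spaced one extent-length
apart, so the spline sees context proportional to the gap. If an anchor
falls off the trace or on missing data, a straight line between the onset
and offset anchors is used. Extents longer than 500 ms are marked missing,
never interpolated: over half a second the pupil is no longer predictable.
After no further blink is found, samples deviating more than 3 SD from the
trace mean or moving faster than the onset threshold are marked missing,
and missing runs derived in this call are widened by 20 ms margins.

Two numerical choices deserve emphasis.

**Noise-calibrated thresholds.** No fixed velocity threshold transfers
across arbitrary-unit scales. Eyelid-driven velocities exceed both
measurement noise and physiological pupil change by one to two orders of
magnitude, so the thresholds are placed at 6 robust SDs of the
smoothed-velocity noise. The noise SD is estimated as the MAD of successive
differences, maximized over 10 contiguous segments of the trace — the
segment maximum is what keeps the estimate from being dragged down by
smooth interpolated stretches when the procedure re-examines its own
output. `vt_start`/`vt_end` scale these thresholds multiplicatively for
recordings that need manual adjustment.

**Idempotence by fixed-point iteration.** Cleaning changes the trace, and
any data-driven rule applied to the cleaned trace could flag something new.
The full pass (threshold calibration, recursive detection and
interpolation, the outlier sweep — itself iterated until it marks nothing —
and gap margins) is therefore repeated until the trace stops changing. The
returned trace is a fixed point of the pass, so applying the function to
its own output is a no-op. A consequence worth knowing: margins are applied
around missingness *derived during the call* (blink extents, rejected
outliers, gaps a blink spans); an isolated dropout with no velocity
signature keeps its original extent rather than growing by another margin
on every re-run.

The simulator retains each trial's pre-injection trace, so reconstruction
error is measurable exactly. Over 200 simulated single-blink trials the
median maximum absolute error across the blink extent stays below 5% of the
trace's dynamic range; interpolation cannot (and should not) reproduce the
measurement noise itself, which bounds what any reconstruction can achieve.

## The rest of the preprocessing chain

The chain order is enforced by a stage marker on the table: blink
reconstruction (needs the native sampling rate) before downsampling, unit
conversion before baseline correction, exclusion last. Stages may be
skipped, never reordered.

* **Downsampling** is block-mean with a dropped trailing partial block;
  means ignore missing cells, an all-missing block is missing. Block
  averaging is itself a box low-pass, so no separate anti-alias filter is
  applied — at the rates that matter here (effects far below 10 Hz) the
  distinction is irrelevant, and block means keep missing-data semantics
  simple.
* **Unit conversion** fits `mm = a * units^b` by least squares on the log
  scale (the relation between recorded units and true diameter is monotone
  but not linear); a linear form is available. The fit warns if it is not
  monotone over the calibrated range, and conversion outside that range
  warns but proceeds.
* **Baseline correction** subtracts (recommended) or divides by the mean
  pupil size over a short pre/peri-onset window, default the first 50 ms of
  the epoch — short, because a long baseline window is more likely to
  contain artifacts. Subtractive correction makes every trial's
  baseline-window mean exactly 0 (divisive: 1). A side effect documented
  but deliberately not modelled: baseline correction induces
  regression-to-the-mean contingencies between baseline size and the
  corrected response, so correlations between the two need care.
* **Trial exclusion** z-scores the per-trial baselines within participant
  (sample SD, n−1) and drops trials with |z| > 2 or a missing baseline. On
  standard-normal baselines this removes the 4.55% two-tailed Gaussian tail
  mass (slightly less in small samples, where the estimated SD absorbs the
  outliers). A zero-variance participant gets z = 0 throughout, with a
  warning rather than an exclusion.

## Data-quality metrics

The four recommended visual checks have quantitative analogues in
`qc_report()`, computed per participant and collapsed across conditions so
quality is judged without seeing the effect of interest: the spike-trial
fraction (a trial spikes if any sample falls more than 5 cross-trial SDs
below the cross-trial mean trace; flag above 5%), the missing-sample
fraction, the baseline distribution (mean, SD, skew), blink counts per
trial by condition (from ground-truth events when available, else maximal
missing runs of at least 50 ms as a proxy), and gaze deviation from the
display centre in degrees. Condition imbalance flags use an advisory
heuristic — a max pairwise condition difference above 25% of the grand
mean — never an inferential test: the field's standard here is transparent
reporting, not automated exclusion.

## Statistical procedures

All three procedures share one model contract: a linear mixed-effects model
with by-participant random effects, Wald z = estimate/SE, and
two-tailed p from the normal approximation (consistent with reporting z
statistics; no degrees-of-freedom correction). `fit_lmm()` wraps `lme4`.

**Predetermined window** (`window_test()`): average the dependent series
over an a-priori window per trial, fit one model. No correction needed; the
cost is committing to the window before seeing the data.

**Cluster-based permutation** (`cluster_permutation_test()`): per-sample
tests give clusters of contiguous samples with p below alpha and a constant
z sign; condition labels are then shuffled within participant (preserving
the participant structure under the null), the scan re-run, and the maximum
false-alarm cluster size recorded per permutation. A cluster's p-value is
`(1 + #{null >= size}) / (1 + n_permutations)` — the add-one rule keeps
p at least `1/(n_permutations + 1)`. The max-cluster null gives family-wise
control; a pooled all-clusters null is available by flag. Within-participant
shuffling and the max-statistic choice are decisions the underlying
literature leaves open; both are configurable.

**Four-fold cross-validation** (`crossval_test()`): rows are split
deterministically in an interleaved pattern (row i to test fold
`(i-1) mod 4 + 1`), so each fold trains on exactly 75% of rows. Per fold,
per-sample random-intercept fits on the training rows select the sample
with the largest |z| (ties to the lowest index — |z| rather than signed z so
negative-going effects are localizable); each held-out trial is then
evaluated at its own fold's sample, and a single final model with
by-participant random intercepts and slopes (the recommended structure, and
the default) is fitted to the assembled values. The procedure is repeated
per fixed effect, and contains no randomness: identical inputs give
identical results.

### The per-sample engine

A per-sample scan inside a permutation scheme multiplies model fits into
the millions, which general mixed-model software cannot sustain. The
package therefore ships a compiled profiled-REML fitter for the
random-intercept model: all samples share the design matrix and grouping,
so per-group aggregates are computed once and each sample reduces to a 1-D
golden-section search over the variance ratio, each evaluation using the
blockwise Sherman–Morrison identity. The fitter solves the same REML
problem as `lme4` for this model — the test suite checks agreement to five
decimals, including under missing data — at microseconds per fit. It powers
localization and the permutation engine; final models and user-facing fits
go through `lme4`. An aggregated per-participant engine (per-participant
slope, one-sample t across participants) is available for the permutation
scan as a faster, coarser alternative.

### Calibration, honestly

On null simulations the cluster test's family-wise error sits comfortably
at alpha. The cross-validation test deserves a franker statement: the
selection step leaks a little variance into the final test, because each
trial helps choose *other* folds' tested samples and then re-enters the
final model at a correlated sample. Under nulls whose time axis has low
effective dimensionality (smooth trends plus weak independent noise — which
is what pupil data looks like), this inflates the variance of the final
estimate above its nominal standard error. With the recommended
random-slopes final model the measured type-I error at this package's
simulated study conditions stays within the 95% binomial band of alpha =
.05 (6.0% over 300 nulls); with an intercept-only final model it runs
higher (8.0% here, 12% under a two-condition design). Practical guidance:
keep random slopes in the final model, and treat p-values within a factor
of two of alpha as soft evidence. The tests and the acceptance script
recompute these rates rather than quoting them.

## The synthetic-data generator

`simulate_dataset()` produces the structure the analyses assume, with known
ground truth: per trial, a participant intercept (N(1800, 100) arbitrary
units), slow sinusoidal arousal drift (amplitude 60 units, 10 s period,
random phase — slow waves of roughly a hundred units peak-to-peak, echoing
published example recordings), a trial-to-trial baseline shift (SD 50), a
condition effect that follows a gamma-shaped response kernel
(unit peak 1000 ms after the effect-window onset, the canonical latency for
stimulus-evoked dilation) restricted to the effect window (default
750–3000 ms), and white measurement noise of 1 unit per sample at 1000 Hz
(video-based pupillometry is precise; variability is dominated by
physiology). Blinks arrive as a per-trial Poisson count (rate 1) with
uniform 100–400 ms closed durations and 10 ms eyelid ramps — sharp drop,
missing run, sharp rise — and the pre-injection trace is kept for oracle
scoring. Gaze jitters around the display centre with 0.3 deg SD. Condition
labels (near/medium/far coded −1/0/1) are balanced within participant and
shuffled deterministically under the seed.

What the simulator does not emulate — and hence what passing tests do not
establish about real data: pupil foreshortening error, post-blink and
post-saccadic constrictions, luminance-driven responses, 1/f-structured
physiological noise beyond the single drift component, binocular
recordings, and session-level artifacts (slipping headbands, makeup).
Parameters are all exposed; the defaults define the package's reference
conditions and are used unchanged by the test suite.

Problem sizes in the tests are chosen for a desk-scale run: calibration
studies use a reduced grid — 500 ms epochs at 1000 Hz, downsampled by 10 to
50 samples, 10 participants x 20–21 trials — which exercises the identical
pipeline at a fraction of the cost of the full 3000 ms design; the
blink-reconstruction oracle runs at the full grid over 200 single-blink
trials.

## Known limitations

* Blink detection assumes monocular input and a drop–gap–rise morphology;
  partial occlusions that only attenuate measured size (no velocity
  signature) are caught, if at all, by the 3 SD amplitude sweep.
* The power-law calibration is a two-parameter summary of a device-specific
  relation; it extrapolates poorly outside the calibrated range (hence the
  warning).
* The cross-validation test's residual anti-conservativeness under
  intercept-only final models is structural to the procedure, not fixable
  by implementation; see the calibration section.
* Parsing supports an ASCII dialect (documented in `message_protocol()`),
  not vendor binary formats.
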