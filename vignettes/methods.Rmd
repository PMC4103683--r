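---
title: "Methods: ratiometric calcium and mating-behavior analysis in spicula"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ratiometric calcium and mating-behavior analysis in spicula}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spicula)
```

`spicula` analyses male *C. elegans* mating at two levels: dual-channel
calcium imaging of the cells that drive ejaculation, and hand-scored
behavioral ethograms of the mating sequence (insertion, valve opening,
sperm release, retraction, re-copulation). This vignette explains the
models, the tunable parameters, the synthetic-data generator that stands in
for recordings, and the design decisions taken where more than one
reasonable convention exists.

## The ratiometric ΔF/F₀ model

A recording consists of per-frame mean gray levels for a green (G-CaMP) and
a red (mDsRed) ROI tracked on the cell, plus same-sized background ROIs on
the bacterial lawn. The processing chain is:

1. **Background subtraction** (`subtract_background`), per frame and per
   channel. Gray levels are non-negative, so negative differences clip to
   zero; more than 1% clipped samples triggers a warning, since that level
   of clipping suggests a mis-placed background ROI.
2. **Bleach correction** (`fit_bleach_decay`, `correct_red`). G-CaMP
   photobleaching is negligible over these sub-minute recordings, but
   mDsRed bleaches appreciably. We fit the standard mono-exponential model
   `red(t) = A·exp(−t/τ) + C` by nonlinear least squares
   (`minpack.lm::nlsLM`, initialized from a log-linear regression with the
   offset pinned just below the series minimum; convergence tolerances are
   set so noiseless exponentials are recovered to better than one part in
   10⁶). The corrected series is `red(t)·model(0)/model(t)` — normalizing
   to the t = 0 model level keeps early-recording baselines unbiased. A
   constant red series returns the degenerate model (amplitude 0, offset =
   mean, τ undefined), under which correction is the identity. The decay
   family is a configuration point in principle; mono-exponential-plus-
   offset is the default because it is the standard fluorophore bleaching
   model and the only one the data constrain.
3. **Ratio and baseline** (`ratiometric_dff`). `r(t) =
   green(t)/corrected_red(t)`; `F₀` is the mean of `r` over a baseline
   window; `%ΔF/F₀ = 100·(r − F₀)/F₀`. The baseline window defaults to the
   2 s preceding the first insertion event (truncated at the recording
   start, minimum 5 samples): "initial fluorescence" is deliberately
   anchored to the pre-stimulus epoch so the transient itself never leaks
   into its own reference. Whether one ratios green over adjusted red or
   adjusts the ratio directly is ambiguous in common practice; we implement
   green/corrected-red. By construction the baseline-window mean of ΔF/F₀
   is zero (to 10⁻⁹), and ΔF/F₀ is invariant under rescaling both channels
   by a common constant — both are tested properties.

Restrained single-indicator preparations (no red reference) use
`single_channel_dff` against the green baseline, and `restrained_summary`
reports the largest absolute change from time point 0 plus the SD of ΔF/F₀
over a fixed (default 60 s) window.

## Event-aligned kinetics

All transient statistics are aligned to the spicule-insertion event.

- **Onset** (`detect_onset`): first time at which ΔF/F₀ exceeds baseline
  mean + k·SD (default k = 2) and stays above threshold without a net
  decrease for m consecutive samples (default m = 3). "Begins to increase"
  has no unique definition; a sustained threshold rule is the conventional
  choice and both constants are exposed. The detected onset necessarily
  trails the true onset by about `threshold/slope`; the test suite asserts
  that lag's sign and bound rather than pretending it is zero.
- **Insertion-to-peak latency** (`peak_latency`): argmax of ΔF/F₀ over a
  post-insertion window (default 30 s, covering intromission through
  release), ties broken to the earliest sample because latency is a
  minimum-time quantity.
- **Rise slope** (`rise_slope`): ordinary least-squares slope of the raw,
  unsmoothed ΔF/F₀ between onset and peak ("slope of the line" is read as a
  straight-line fit).
- **Second rises** (`second_rise_features`): for biphasic signals (sex
  muscles), onset is re-detected after the inter-peak trough (sought within
  10 s of the first peak so post-release oscillations are not mistaken for
  the dip), the second peak is the subsequent argmax, and the slope spans
  the two.
- **Post-peak 15 s slope** (`post_peak_15s_slope`): OLS slope over the 15 s
  after the global peak, a window chosen to include sperm release. Windows
  truncated by the end of the recording are computed on the available
  samples and flagged, not dropped.

`extract_kinetics` assembles these per bout, with two robustness rules that
matter only for noisy data. First, a bout whose onset rule never fires —
or whose trace never rises to twice the detection threshold above baseline,
i.e. only grazes the threshold band — is flagged `no_transient` and
contributes no features: the same convention an analyst applies by only
quantifying recordings with a visible transient. Without it, a rare
low-amplitude bout turns the windowed argmax into a uniform draw over the
search window and corrupts cohort means. Second, the
peak search is confined to the contiguous suprathreshold epoch that starts
at the onset, with hysteresis (the end-of-epoch test arms only once the
trace reaches twice the threshold excursion), so a lone noise spike far
from the transient cannot pose as the peak and noise dips during a slow
rise cannot cut the epoch short. For the rise slope, the OLS segment
endpoints are placed using a centered moving average of width 7 samples
(odd width, endpoint placement only — the fitted values are always raw):
ending the fit at the raw argmax sample would include a sample whose noise
is positively selected by the max operation, which measurably biases
cohort-mean slopes upward; ending half a smoothing window before the
smoothed argmax keeps every fitted sample on the rising limb. Segments
shorter than 6 samples fall back to the plain onset-to-peak fit.

`summarize_cohort` reports mean ± sample SD (n − 1 denominator) per
feature with n, one row per cohort.

## The synthetic-data generator

The generator defines the conditions under which the pipeline is validated.
`make_preset` transcribes the reference kinetics of each cell type
(insertion-to-peak latency and initial rise slope, mean ± SD): SPC
1.3 ± 0.52 s at 45 ± 13 %/s, gonadal valve 1.8 ± 0.79 s at 60 ± 14 %/s,
SPV/SPD 4.0 ± 1.0 s at 21 ± 14 %/s, PCA 6.3 ± 0.56 s at 15 ± 2.9 %/s,
socket cells 1.7 ± 0.36 s at 94 ± 18 %/s, sex muscles 1.3 ± 1.7 s at
155 ± 82 %/s with a second peak at 11 ± 3.9 s and 46 ± 19 %/s, plus a
zero-amplitude `ray_flat` control. Behavioral latencies ride along in the
event log: valve opening 6.9 ± 1.5 s after insertion, sperm release
starting ~15 s after insertion and lasting ~17 s.

Modeling choices, in the order they matter:

- **Waveform.** The source traces are shown but never parameterized, so the
  transient is piecewise linear: flat baseline, linear rise from onset to
  peak, linear decline, optional sustained plateau (PCA stays elevated
  after release), optional additive second rise and damped post-release
  oscillation (sex muscles), optional sigmoidal rise shape. The latency and
  straight-line slope metrics are shape-robust, which is what licenses this
  simplification.
- **Decline rate.** By default the decline mirrors the rise
  (`decay_rate = rise_slope`). This makes the peak locally symmetric, and a
  symmetric peak is the unique shape for which the sample-argmax latency
  estimator is unbiased under additive noise at any noise level — the
  property the parameter-recovery tests rely on. The valve and socket
  presets instead keep the slow, protracted declines their recordings show
  (6 and 4.3 %/s; the valve's decline must span the 15 s post-peak window
  for the decline-slope contrast between intact and spicule-tips-cut males
  to be meaningful). The cost is stated plainly: under noise, the argmax
  latency of a slow-declining transient is biased late by a few tenths of a
  second, so those two presets are validated by noiseless round-trips and
  event-log latencies rather than by noisy ΔF/F₀ latency recovery.
- **Per-bout variability.** Latencies (as onset-to-peak durations) and
  slopes are drawn lognormal with the tabulated arithmetic mean and SD.
  Lognormal draws are strictly positive with exact first two moments, so
  cohort means recover the nominal values without the truncation bias a
  normal draw would need; durations and slopes are physiologically
  non-negative quantities with right-skewed spreads, for which lognormal is
  the standard choice.
- **Channels and noise.** `green = background + F0g·(1 + noise +
  transient/100)`; `red = background + F0r·(floor + (1 −
  floor)·exp(−t/τ))·(1 + noise)` with τ = 30 s and floor 0.2. Noise is
  additive Gaussian, SD = 3% of F₀ by default, independent per sample and
  channel — the simplest model sufficient for recovery testing. Green
  bleaching is off by default (negligible over these recordings).
- **Sampling.** dt = 0.05 s (20 Hz) and 45 s bouts by default; the
  acquisition rate and recording length of the original videos are not
  stated anywhere, so both are free parameters.
- **Seeds.** Every generator is a pure function of (parameters, seed), and
  restores the caller's RNG state. Cohorts derive per-bout seeds by drawing
  sub-seeds from the master-seeded stream rather than by a
  master-plus-index counter: sequential Mersenne-Twister seeds produce
  measurably correlated first draws across a cohort, which inflates
  cohort-mean variance beyond what a 2·SD/√n tolerance assumes.
- **Trial populations** (`simulate_trials`): per-male commencement,
  insertion latency, refractory period (default lognormal, mean 720 s,
  SD 390 s), transfer duration, and outcome category from stage-success
  probabilities (defaults 0.92 for valve opening and 0.71 for release,
  matching intact-male proportions). Second-mating release success and
  progeny counts scale with `min(1, refractory/720)`, encoding sperm-stock
  recovery over the refractory period — this is the mechanism behind the
  tested property that males binned into the long-refractory group sire
  progeny at the second mating more often than the short group.
- **Image stacks** (`render_frames`/`extract_roi_means`): in-memory
  per-frame pixel arrays whose ROI means reproduce the trace exactly, with
  an optional drifting ROI and its track, used to validate the ROI-means
  round trip at the pixel level.

What the generator does **not** emulate: motion artifacts and ROI tracking
error beyond rigid drift, indicator nonlinearity and saturation, shot-noise
scaling with signal level, correlated (non-white) noise, photobleaching of
the green channel, and hermaphrodite-side behavior. Passing the recovery
tests therefore demonstrates that the analysis chain is correct and
well-calibrated for peaked transients under additive noise — not that it
would be unbiased on arbitrarily shaped real recordings.

## Behavioral scoring conventions

- Time is seconds from trial start; intervals are half-open `[start, end)`
  and durations are `end − start`; all interval metrics are invariant under
  a global time shift (tested).
- **Sperm-transfer ranking**: outcome category (0 uterine ejaculation,
  1 insertion without ejaculation, 2 ectopic ejaculation, 3 neither) plus
  time-to-insert divided by the 300 s cap. Males that never insert within
  the cap contribute the full 1.0 (censored at cap), which keeps the score
  monotone: within a category later insertion scores strictly higher, and a
  category-k male at the cap scores below any category-(k+1) male.
- **Refractory period**: first-to-second insertion interval; undefined (NA,
  never zero) with fewer than two insertions. Binning splits at 540 s with
  half-open convention [180, 540) vs [540, 1800]; values outside are
  flagged rather than silently binned.
- **Time at vulva** counts only pre-insertion contact; a contact spanning
  the insertion is truncated at it (whether the insertion-bearing contact
  counts is ambiguous; truncation is the conservative reading).
- **Second-insertion metrics** clip inserted intervals to the 30 s window
  after the second insertion and count re-inserts/retractions in the
  following 60 s, because operated males insert and retract repeatedly.
- **Sustained transfer** is release ≥ 10 s (wild-type transfer lasts
  ~17 s); missing release records classify as not sustained.
- Undefined metrics propagate as explicit `NA`s throughout.

## Statistics

All procedures are implemented directly; the established R implementations
(`fisher.test`, `wilcox.test`, `t.test`, `aov`, `var.test`) appear in the
test suite as independent oracles only.

- **Fisher's exact test**: with margins fixed, the two-sided p-value sums
  the hypergeometric probabilities of every admissible table whose point
  probability does not exceed the observed table's (probability-mass rule,
  with a 10⁻⁷ relative guard against floating-point ties). This rule is
  stated explicitly because mid-p and tail-doubling definitions give
  different numbers; it is the definition that reproduces conventional
  printed p-values, and it matches brute-force enumeration to 10⁻¹² on all
  tested tables. Empty margins return p = 1 with a warning.
- **Mann–Whitney U**: midranks for ties; exact two-sided p by full
  enumeration of group assignments (twice the smaller tail, capped at 1)
  when n₁+n₂ ≤ 16 and no ties are present; otherwise a tie-corrected
  normal approximation with continuity correction. The two modes agree
  within 0.02 on 8-vs-8 samples (tested over 100 draws).
- **Paired t**: standard t on differences, df = n − 1; zero-variance
  differences are an error, not a p-value.
- **One-way ANOVA + Newman–Keuls**: the stepwise studentized-range
  procedure on ordered means, quantiles from `ptukey` (never lookup
  tables), Tukey–Kramer standard errors for unequal n, and the step-down
  protection rule (a pair is tested only when every containing range was
  significant). **Bonferroni** variant: all-pairs pooled-variance t tests
  with p multiplied by k(k−1)/2 and capped at 1.
- **Variance-ratio test**: larger variance over smaller, two-sided p as
  twice the upper F tail.
- p-values are never rounded internally; rounding happens only at
  presentation.

## Problem sizes and runtime

The validation suite runs at deliberately modest sizes: recovery cohorts of
n = 100 bouts at 20 Hz × 45 s per preset (the scale at which a 2·SD/√n
tolerance is meaningful), 10⁴ null simulations for the Fisher type-I check,
and full-enumeration oracles up to n₁+n₂ = 16. These sizes keep the entire
suite in the tens of seconds on one CPU while leaving every statistical
bound non-trivial.

## Known limitations

- The argmax latency estimator is biased late on slow-declining transients
  under noise (valve, socket presets); their noisy-cohort latencies are
  deliberately not used as calibration checks.
- The onset detector's threshold lag (~threshold/slope) is inherent to any
  sustained-threshold rule; onsets are therefore reported as detected, not
  back-extrapolated.
- Real-recording phenomena outside the generator's scope (listed above) are
  untested by construction.
- The Newman–Keuls procedure does not control the family-wise error rate
  under all configurations (a known property of the method); it is provided
  because it is the convention for transient-kinetics tables, with
  Bonferroni available as the conservative alternative.
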