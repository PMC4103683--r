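# spicula

Quantitative analysis of male *Caenorhabditis elegans* copulation and
ejaculation, for researchers who score mating behavior on video and record
intracellular Ca²⁺ with genetically encoded indicators during it.

During a successful mating a male inserts his copulatory spicules into the
hermaphrodite vulva, the gonadal valve opens to move sperm from the seminal
vesicle into the vas deferens (initiation), sperm drains out of the cloaca
into the uterus (release), and a refractory period follows before the male
re-copulates. `spicula` implements the measurement chain used to dissect
this circuit:

- **Ratiometric ΔF/F₀ traces.** Raw per-frame ROI mean gray levels from a
  dual-channel recording (G-CaMP green, Ca²⁺-insensitive mDsRed red, plus
  background ROIs on the bacterial lawn) are background-subtracted; the red
  channel's photobleaching is removed by fitting
  `red(t) = A·exp(−t/τ) + C` and rescaling to the fit's t = 0 level; the
  green:corrected-red ratio r(t) is then expressed as
  `%ΔF/F₀ = 100·(r(t) − F₀)/F₀`, with F₀ the mean ratio over a baseline
  window just before spicule insertion.
- **Event-aligned transient kinetics.** Onset (baseline mean + k·SD,
  sustained for m samples), insertion-to-peak latency (windowed argmax),
  straight-line (OLS) rise slope in %ΔF/F₀ s⁻¹, biphasic second rises, and
  the post-peak 15 s slope that brackets sperm release; cohort summaries as
  mean ± SD with n.
- **Mating ethogram scoring.** Refractory period (1st-to-2nd insertion
  interval), the composite sperm-transfer ranking
  (outcome category 0–3 + time-to-insert/300 s), mating drive, time at
  vulva, vulva passes, insertion-time metrics, the ≥10 s sustained-transfer
  rule, refractory binning at 9 min, and per-insertion potency.
- **Exact small-sample statistics,** implemented from first principles so
  that printed p-values on printed tables reproduce digit-for-digit:
  two-sided Fisher's exact test by hypergeometric enumeration
  (probability-mass rule), exact/approximate Mann–Whitney U, paired t,
  one-way ANOVA with Newman–Keuls (studentized range) or Bonferroni
  follow-ups, and the two-sided variance-ratio F test.
- **A synthetic-data generator** producing dual-channel bouts, event logs,
  image stacks, mating-trial populations and contingency outcomes with
  known ground truth, so every stage above is testable end to end without
  any recording.

## Worked example

Simulate one SPC-neuron bout (insertion at 5 s, 20 Hz, 3% noise), run the
full trace pipeline, and read off its kinetics:

```r
library(spicula)

b <- simulate_bout(make_preset("spc"), insertion_time_s = 5,
                   duration_s = 45, seed = 7)
f <- process_bout(b$trace, b$events)
cat(sprintf("onset %.2f s | insertion-to-peak %.2f s | rise slope %.1f %%/s\n",
            f$onset_s - 5, f$insertion_to_peak_s, f$rise_slope))
#> onset 0.70 s | insertion-to-peak 2.95 s | rise slope 30.7 %/s
```

This bout's generator-side truth was a 2.98 s latency and a 30.8 %/s slope
(each preset draws per-bout kinetics around its nominal mean), so the
pipeline recovered both within its sampling resolution. A cohort averages
back to the preset values — nominally 1.3 ± 0.52 s and 45 ± 13 %/s for SPC:

```r
co <- simulate_cohort(make_preset("spc"), n = 100, seed = 11)
run_pipeline(co, group = "SPC")$summary
#>   group   n insertion_to_peak_s_mean insertion_to_peak_s_sd rise_slope_mean ...
#> 1   SPC 100                     1.39                  0.506            47.3
```

The statistics module reproduces printed contingency results exactly; for
valve opening in 12/13 mock-cut versus 8/15 spicule-tips-cut males:

```r
fisher_exact(contingency_2x2(12, 1, 8, 7))$p
#> [1] 0.03768116   # prints as p = 0.0377
```

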