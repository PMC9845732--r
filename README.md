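# diffrhythm

Differential circadian rhythmicity analysis for two-group expression
timecourses.

Peripheral tissues such as liver express thousands of transcripts with
~24-h rhythms, and interventions like a high-fat diet can raise or
flatten those rhythms, shift their timing, or abolish them. `diffrhythm`
is for experiments that sample two groups (a control and a treatment) at
a handful of Zeitgeber times with a few replicates per time — e.g. two
diet groups × ZT 0, 4, 8, 12, 16, 20, 24 × 3–5 animals — and ask, per
gene, *how* the rhythm differs between groups.

## What it computes

**Cosinor fit.** For one group, expression is modelled as

    y(t) = M + A · cos(2π/T · (t − φ)) + ε

with fixed period `T = 24` h: `M` (mesor) is the rhythm-adjusted mean,
`A ≥ 0` (amplitude) the distance from mesor to peak, and `φ` (acrophase,
hours in `[0, 24)`) the clock time of the peak. The model is intrinsically
linear in `(1, cos ωt, sin ωt)`, so `cosinor_fit()` solves it by ordinary
least squares and propagates uncertainty to `(M, A, φ)` by the delta
method; a Levenberg–Marquardt route (`method = "nls"`) is kept as a
cross-check. A 2-df F test gives the zero-amplitude (any-rhythm) p-value.

**Offset model.** `cosinor_diff()` fits both groups jointly with the
treatment parameters expressed as offsets from the reference:

    y(t) = (M + g·ΔM) + (A + g·ΔA) · cos(2π/T · (t − φ − g·Δφ)),  g ∈ {0,1}

Each offset gets a Wald 95% CI on `n − 6` df; an offset whose CI excludes
0 is called a significant group difference. `nested_model_select()` runs
the matching extra-sum-of-squares F tests to decide which parameters need
to be group-specific.

**Categorization.** `categorize_all()` classifies every transcript by BIC
weights over five harmonic-regression models — arrhythmic, loss (rhythm
in the reference only), gain (treatment only), same (one shared rhythm),
change (rhythmic in both, different parameters) — after a low-count
filter (mean count ≥ 25 by default) and a `log2(x+1)` transform for
counts, and exports bar-chart counts plus circular-plot records
(log2 amplitude ratio, phase difference).

**qPCR quantification.** `ddct_quantify()` implements 2^−ΔΔCt relative
quantification with a phase-specific calibrator: light-phase samples are
normalized to the reference group's mean at ZT 0, dark-phase samples to
its mean at ZT 12.

**Report summaries.** `percent_increase()`, `percent_decrease()`,
`percent_difference_of_means()` and `combined_group_test()` (pooled
Student t) reproduce report-style percent-change statements and
combined-timepoint comparisons.

**Synthetic data.** `make_study_design()`, `plant_categories()`,
`simulate_expression()` (Gaussian or negative-binomial counts) and
`simulate_qpcr_ct()` generate timecourses with known truth so the whole
pipeline is testable without any external dataset.

## Worked example

```r
library(diffrhythm)
design <- make_study_design(reps = 5)          # 2 diets x 7 ZT x 5 mice
set.seed(2024)
truth <- plant_categories(c(CHANGE = 1), sigma = 0.4, snr = 5)
sim <- simulate_expression(design, truth, noise = "gaussian", seed = 2024)
y <- sim$matrix[1, ]

fit <- cosinor_diff(design$time_h, y, design$group)
summary(fit)
#> Two-group cosinor: HFD vs AIN93G (reference); n = 70, df = 64
#>  parameter ref_estimate  ref_se trt_estimate  trt_se difference    ci_lo
#>      mesor        9.243 0.07407        9.373 0.07109      0.130 -0.07927
#>  amplitude        1.886 0.10900        4.573 0.10660      2.686  2.37500
#>  acrophase        7.600 0.20310       17.910 0.07856     10.310  9.87100
#>    ci_hi         p
#>   0.3393 2.191e-01
#>   2.9970 9.223e-26
#>  10.7500 2.194e-51
```

The treatment group's mesor does not differ (ΔM CI crosses 0, p = 0.22),
but its amplitude is 2.69 units higher and its peak comes 10.3 h later,
both with CIs that exclude 0 — a "change of rhythm" gene.

```r
percent_offset_summary(fit)
#>   parameter reference treatment direction percent percent_exact
#> 1     mesor  9.243142  9.373139  increase       1      1.406413
#> 2 amplitude  1.886314  4.572766  increase     142    142.418083

categorize_all(sim$matrix, design)
#> Differential-rhythmicity categorization of 1 features
#>  ARRHY   LOSS   GAIN   SAME CHANGE
#>      0      0      0      0      1
```

`run_pipeline(out_dir)` chains simulate → fit → compare → categorize →
summarize and writes each stage's TSV plus a JSON manifest.

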