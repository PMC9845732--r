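---
title: "Methods: two-group cosinor analysis and rhythm categorization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-group cosinor analysis and rhythm categorization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffrhythm)
```

This vignette is the package's account of the statistical machinery: the
models, the conventions behind every reported number, the defaults and
why they are what they are, and what the synthetic-data checks do and do
not establish.

## The cosinor model

A single group's expression timecourse is modelled as

$$y_i = M + A \cos\!\Big(\frac{2\pi}{T}(t_i - \varphi)\Big) + \varepsilon_i,
\qquad \varepsilon_i \sim N(0, \sigma^2),$$

with the period fixed at $T = 24$ h — the design samples one cycle at
4-h resolution, which cannot support period estimation, and the
entraining light-dark cycle pins the expected period. The parameters are
the **mesor** $M$ (rhythm-adjusted mean), **amplitude** $A \ge 0$
(mesor-to-peak distance) and **acrophase** $\varphi$ (peak time, hours
in $[0, 24)$).

Because
$A\cos(\omega(t-\varphi)) = \beta_c \cos\omega t + \beta_s \sin\omega t$
with $\beta_c = A\cos\omega\varphi$, $\beta_s = A\sin\omega\varphi$, the
model is *intrinsically linear*. `cosinor_fit()` therefore solves the
harmonic regression by ordinary least squares and maps
$(\beta_0, \beta_c, \beta_s)$ to $(M, A, \varphi)$, with standard errors
by the delta method from the OLS covariance. The
`method = "nls"` route refits the same sum of squares by
Levenberg–Marquardt in the $(M, A, \varphi)$ parameterization; at the
optimum the two routes coincide (the delta-method covariance equals the
Jacobian-based NLS covariance under a smooth reparameterization), and
the test suite asserts their agreement on every random dataset it draws.
The iterative route exists as an independent cross-check and as the
template for constrained fits that are genuinely nonlinear (below).

Conventions that make the representation unique:

* $(M, A, \varphi)$ and $(M, -A, \varphi + T/2)$ give identical curves;
  results are canonicalized to $A \ge 0$, $\varphi \in [0, T)$.
* The zero-amplitude test is the 2-df extra-sum-of-squares F test of
  $\beta_c = \beta_s = 0$.
* The delta method divides by $A$, so phase uncertainty explodes as the
  rhythm collapses. When the zero-amplitude p-value is $\ge 0.5$ the
  acrophase is flagged unstable and its SE/CI suppressed rather than
  reported as a large meaningless number.
* Confidence intervals use the $t$ distribution with $n - 3$ df,
  matching small-sample nonlinear-regression practice at $n = 35$ per
  group per gene.

Degenerate inputs: a constant response returns $A = 0$, an undefined
acrophase and amplitude p-value 1 by convention; designs whose times
collapse modulo the period are rejected as rank-deficient; fewer than
four distinct sampling times leave no residual df and are rejected at
design validation.

## The two-group offset model

Group differences are inferred from the joint six-parameter model

$$y = (M + g\,\Delta M) + (A + g\,\Delta A)
\cos\!\Big(\frac{2\pi}{T}(t - \varphi - g\,\Delta\varphi)\Big),$$

where $g$ indicates the treatment group. Writing the treatment
parameters as offsets from the reference makes each offset's 95% CI a
direct test of the group difference: the offset is called significant
when its CI excludes 0, which is equivalent (exactly, by construction)
to its Wald $p \le 0.05$ on $n - 6$ df. The full offset model is again
intrinsically linear (six harmonic columns, per-group), so
`cosinor_diff()` fits it exactly and reaches the offset scale by the
delta method; `method = "nls"` cross-checks via Levenberg–Marquardt. On
balanced designs the offset point estimates equal the difference of
separate per-group fits, a property the tests assert to $10^{-6}$.

The acrophase offset is wrapped into $(-T/2, T/2]$ — an 18-h delay and a
6-h advance are the same phase relation — and is reported as unstable
when either group is effectively arrhythmic (zero-amplitude p $\ge$
0.5), because a phase difference against a collapsed rhythm is not
identified. Treatment-side SEs are taken from the joint fit.

`nested_model_select()` asks, per parameter, whether the offset is
needed: each offset in turn is fixed at zero and the reduction tested
against the full model by the extra-sum-of-squares F test at
$\alpha = 0.05$. Of the constrained models, four are linear
(no constraint; all offsets zero; only $\Delta M$ free; common mesor
with free per-group harmonics) and are solved exactly; the mixed cases
(e.g. shared phase, free amplitudes) are genuinely nonlinear and go
through Levenberg–Marquardt started from the full-model solution.

No multiple-testing correction is applied across a small qPCR panel;
transcriptome-scale work goes through the categorization route, which
controls complexity through BIC rather than per-test error rates (an
optional BH-controlled F-test screen, `rhythm_ftest()`, is provided but
off the main path).

## BIC-weight categorization

Per transcript, five least-squares models are compared:

| model  | mean structure                          | k |
|--------|------------------------------------------|---|
| ARRHY  | group means                              | 2 |
| LOSS   | group means + harmonics, reference only  | 4 |
| GAIN   | group means + harmonics, treatment only  | 4 |
| SAME   | group means + one shared harmonic pair   | 4 |
| CHANGE | group means + per-group harmonic pairs   | 6 |

with $\mathrm{BIC}_m = n\ln(\mathrm{SSE}_m/n) + k_m\ln n$ and Schwarz
weights $w_m \propto \exp(-\tfrac12\Delta\mathrm{BIC}_m)$. The call is
the argmax model when its weight reaches the cutoff (default 0.6) and,
for rhythmic categories, the fitted amplitude on the analysis scale
reaches the amplitude cutoff (default 0); otherwise the transcript falls
back conservatively to ARRHY. Ties in the best weight go to the simpler
model. Both cutoffs are deliberately exposed configuration rather than
constants: they emulate the defaults of external model-selection
classifiers whose exact values vary across versions, and sensitivity to
them is easy to probe by re-running `categorize_all()` with a different
`rhythm_config()`.

Counts are filtered first — a feature is retained when its **mean** raw
count across all samples is at least 25; "counts of 25 or greater" rules
are ambiguous about pooling, so `mean` is the default with `min` and
`total` available — and then transformed by $\log_2(x+1)$ for variance
stabilization before the least-squares fits (raw passthrough for
already-normalized input). Weights are invariant under positive affine
rescaling of a feature ($y \to ay + b$, $a > 0$), since a common scale
multiplies every model's SSE equally; this is asserted as a test
property. Numerically, per-feature SSEs are floored at
$10^{-12}\sum y^2$ so that interpolating fits cannot produce
$-\infty$ BICs.

## 2^−ΔΔCt quantification

`ddct_quantify()` computes $\Delta Ct = Ct_\text{target} -
Ct_\text{reference gene}$ per sample, calibrates against the **mean**
$\Delta Ct$ of the reference group's baseline samples (a group-level
calibrator matches group-level fold-change figures; a single-animal
calibrator would inject one animal's noise into every value), and
reports $2^{-\Delta\Delta Ct}$. The baseline is phase-specific:
light-phase samples (ZT in $[0, 12)$, plus ZT 24 as the lights-on moment
of day 2) are normalized to the reference group at ZT 0, dark-phase
samples to ZT 12. Amplification efficiency is fixed at 2 — that is the
method — with no standard-curve correction or multi-reference geometric
means.

## The synthetic-data generator

`make_study_design()` reproduces the study geometry: two groups, seven
Zeitgeber times 0–24 h at 4-h steps, a configurable number of replicates
(5 for the qPCR-like arm, 3 for the RNA-seq-like arm). ZT 0 and ZT 24
are distinct samples — different animals on consecutive days — and are
*not* merged; the cosine basis makes them equivalent in expectation
only.

`plant_categories()` draws per-feature truths whose parameter structure
realizes each category (SAME shares everything; LOSS/GAIN zero one
group's amplitude; CHANGE scales the treatment amplitude by 1.8–2.5× and
shifts its phase by 6–12 h; mesors uniform on a mid-range), with
rhythmic amplitudes expressed via the signal-to-noise ratio $A/\sigma$.
Presets $A/\sigma \in \{1, 2, 4\}$ span hard to easy regimes; the
acceptance checks run at $A/\sigma = 4$, where an adequately implemented
classifier should succeed, not at the detection boundary.
`simulate_expression()` adds Gaussian noise on the analysis scale, or —
for the count mode — draws negative-binomial counts with mean
$2^{\text{cosinor}} \times$ library factor (library factors lognormal
with SD 0.1) and dispersion 0.05, giving realistic overdispersion.
`simulate_qpcr_ct()` inverts the ΔΔCt arithmetic so the planted fold
changes round-trip exactly at zero noise.

What the generator does **not** emulate: mean–variance trends across the
dynamic range, correlated noise across genes or across an animal's
samples, asymmetric (non-sinusoidal) waveforms, outlier animals, and
batch structure. Passing the synthetic checks therefore demonstrates
correctness of the estimators and decision rules under the assumed
model, not robustness to everything real tissue data can do.

## Calibration checks and problem sizes

The test suite verifies, at the 7-time × 5-replicate design with
$A/\sigma = 3$: empirical 95%-CI coverage for mesor, amplitude and
acrophase within [0.93, 0.97] and median absolute acrophase error below
0.5 h over 1,000 simulations; and type-I error of each offset test
within [0.035, 0.065] over 2,000 null simulations. Category recovery is
evaluated on five replicate batches of 500 features (100 per category,
$A/\sigma = 4$, three replicates per time as in the sequencing arm), so
each per-category accuracy is estimated from 500 features with roughly
±1% Monte-Carlo error against the 90% requirement. These sizes make the
estimates reproducibly stable while keeping the default test run fast.

## Known limitations

* Exactly two groups; no covariates, no mixed effects, no
  multi-harmonic waveforms, no period estimation.
* Wald/delta-method intervals are first-order; at very low
  signal-to-noise the amplitude interval can cross zero even when the
  rhythm test is significant, and the acrophase interval is suppressed
  rather than profiled.
* The categorization route assumes homoscedastic noise on the analysis
  scale after the log transform; no library-size normalization beyond
  the transform is applied, and whether input counts should be
  pre-normalized is left to the user via the matrix scale tag.
* Missing values are not modelled; rows containing them are dropped
  with a message at matrix validation.
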