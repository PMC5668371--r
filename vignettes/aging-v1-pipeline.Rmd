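---
title: "Models and methods behind the agingV1 pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the agingV1 pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(agingV1)
```

This vignette is the package's own account of its science: the models it
implements, the conventions it adopts where the field's descriptions are
ambiguous, the design of the synthetic-data generator, and the known
limitations of both. Everything quantitative stated here is computed by
the test suite or by `scripts/acceptance.R`; nothing is asserted beyond
what those runs check.

## The scientific problem

In senescent rats, V1 neurons show markedly increased visually evoked and
spontaneous firing, a lower signal-to-noise ratio, and degraded
selectivity for stimulus orientation and motion direction, alongside a
reduced proportion of GABA-positive neurons and lower GAD67 and GABA_A
receptor α1 expression. Analyses of this kind combine three arms —
single-unit electrophysiology, fluorescence histology, and western-blot
densitometry — each with its own estimators and statistics. `agingV1`
implements all three as composable, tibble-in/tibble-out functions, and
pairs them with a seeded generator that produces every input the pipeline
consumes, so each estimator can be validated against planted ground
truth.

## Direction tuning: model and fitting conventions

The tuning model is a baseline plus two Gaussian lobes with shared width
σ, centred on the preferred direction θ0 and the null direction
θ1 = θ0 + 180°:

$$R(\theta) = a_0 + a_1 e^{-\Delta(\theta,\theta_0)^2/2\sigma^2}
  + a_2 e^{-\Delta(\theta,\theta_1)^2/2\sigma^2},$$

where Δ wraps angular differences to (−180°, 180°]. Several points are
under-determined by the usual verbal description, and the package fixes
them as follows:

* **Normalization.** Responses are divided by the curve maximum before
  fitting, so the 0.5 acceptance threshold on the mean squared fitting
  error — and typical good-fit errors of order 0.01–0.1 — live on a
  dimensionless scale, consistent with the magnitudes usually quoted for
  this filter. Whether the published errors were computed on a
  normalized scale is an inference, not a stated fact.
* **Baseline.** `a0` is fixed to the mean of the four lowest points of
  the (normalized) curve, a literal reading of the model's definition,
  rather than fitted. With 15° sampling this rule is exactly consistent
  with the generating model for widths up to roughly σ ≈ 16°; for wider
  curves the Gaussian tails leak into the four lowest points and bias
  the plug-in baseline by a few 10⁻⁴, which the other parameters absorb
  (observed as parameter biases below 10⁻² at σ = 25°). The unit tests
  quantify this; it is irrelevant at the noise levels of real data.
* **Null-lobe constraint.** θ1 is constrained to θ0 + 180° by default,
  removing a degeneracy between the two lobes; `free_theta1 = TRUE`
  relaxes it.
* **Optimization.** Bounded Levenberg-Marquardt (via `minpack.lm`) with
  multi-start initialization: θ0 starts at the primary and the secondary
  circular peak of the curve, σ at 15°, 30°, and 60°; the best mse wins
  and exact ties go to the smaller σ. If the optimizer's larger lobe
  lands on the secondary peak, lobes are swapped so `a1` always marks
  the preferred direction.
* **Degenerate input.** All-zero, all-equal, or non-positive curves are
  flagged (`accepted = FALSE`, zero amplitudes) rather than raised.

## Selectivity indices and response metrics

OSI and DSI are the normalized difference
(R_opt − R_null)/(R_opt − R_spon). The package evaluates R_opt and
R_null on the *fitted* curve (the fit is otherwise unused downstream; a
`from_fit = FALSE` flag switches to raw bins), takes R_spon as the mean
pre-stimulus rate, uses the mean of θ0 ± 90° for the orientation null
(the verbal rule says only "orthogonal"), and clips both indices to
[0, 1] — consistent with reported distributions that never exceed 1.
Neurons whose fitted optimum does not exceed the spontaneous rate have
undefined indices: they are flagged and excluded from selectivity
statistics but retained for SA and SNR.

One convention deserves emphasis: the tuning curve's responses are
already spontaneous-subtracted (the response is defined as the mean
firing rate with spontaneous activity subtracted), and the index formula
subtracts R_spon again in the denominator. The generator's analytic
indices use exactly the same convention, so generation and recovery are
consistent by construction; this is the contract the package implements,
not a claim about the uniquely correct reading.

OR is the maximum and AR the mean of the 24 per-direction mean
responses; SNR = OR / max(SA, 1 spike/s), the floor preventing division
by near-zero spontaneous rates. Whether OR/AR should subtract
spontaneous activity is not stated in the usual verbal descriptions;
the package follows the global response definition (subtracted), which
is also what its generator emulates.

## F1/F0 classification

The cycle histogram uses 32 bins per cycle at the grating temporal
frequency, pooling spikes across repetitions and discarding the final
partial cycle; F0 is the spontaneous-subtracted mean evoked rate
(a `subtract_spontaneous = FALSE` flag reverts to the raw mean), F1 the
amplitude of the histogram's first Fourier harmonic, and a cell is
simple iff F1/F0 > 1 — a ratio of exactly 1 is complex, since the rule
is strictly "greater than". When F0 ≤ 0 the classification is undefined
and the record is flagged out of the class counts.

## The synthetic-data generator

The generator's defaults are the study conditions: group presets carry
the published young/old group statistics (OSI 0.71 ± 0.18 vs
0.48 ± 0.18, DSI 0.48 ± 0.25 vs 0.33 ± 0.17, OR 47.1 ± 27.9 vs
99.1 ± 29.5 spikes/s, SA 3.4 ± 2.6 vs 24.7 ± 11.7 spikes/s, simple-cell
fractions 32/79 and 29/83, n = 79 vs 83), the protocol is 24 directions
× 5 repetitions (within the published 4–6) with a 1-s pre-stimulus
window, and the stimulus lasts 3 s — the source only bounds it below
5 s — at a 2 Hz temporal frequency, inside the published 0.5–16 Hz
range.

* **Index-targeted parameters.** Rather than sampling amplitudes freely,
  each neuron's (a1, a2, σ) are solved in closed form so that the
  analytic OSI/DSI of its noiseless curve equal truncated-normal draws
  with the preset's moments. The two-lobe leakage term couples the
  equations; a fixed-point iteration on w(180°) = w(90°)⁴ converges to
  machine precision in a few steps. Draws with no feasible solution
  (peak below the spontaneous rate, or a negative null amplitude) are
  rejected and redrawn with a bounded retry count. This makes
  parameter-recovery acceptance well-posed: the pipeline's estimates can
  be compared to exact per-neuron truths.
* **Spontaneous activity.** Young SA is a normal truncated at zero
  (small mean, moderate SD); old SA is a lognormal moment-matched to the
  published mean and SD — both keep rates non-negative while hitting the
  printed moments. The feasibility condition (evoked peak above SA)
  conditions the OR draws slightly upward for the young preset; OSI,
  DSI, and SA marginals are unaffected because redraws are triggered
  only by the OR–SA comparison.
* **Spiking.** Trials are inhomogeneous Poisson by thinning, with rate
  max(0, SA + E(θ)(1 + m·cos 2πft)); pre-stimulus epochs are homogeneous
  at SA. With this rate model an unrectified sinusoidal modulation can
  never push F1/F0 above 1 (the ratio equals m ≤ 1), so simple cells
  draw m ∈ [1.2, 2.0] — the rectified-sinusoid regime, giving ratios of
  roughly 1.1–1.35 — and complex cells m ∈ [0, 0.3]. Drawing simple
  cells below m = 1 would make the published "ratio > 1 ⇒ simple" rule
  unsatisfiable, so this is the one place the generator departs from a
  naive modulation-depth-in-[0,1] parameterization.
* **Histology.** Cell maps are homogeneous spatial Poisson processes per
  AOI at the planted NeuN density, each cell independently GABA⁺ with
  the planted probability — the simplest process matching density-only
  summaries. The default AOI geometry (0.05 mm², 61 AOIs per group and
  layer) makes the residual degrees of freedom of the age × layer ANOVA
  equal 600, matching the printed design scale; the exact published AOI
  count is not stated, so this is configuration, not reconstruction.
  Rendered images place Gaussian blobs on co-registered channels with
  additive noise; sub-pixel blobs become single-pixel impulses.
* **Blots.** Lane optical densities are lognormal; a helper computes the
  target-band moments such that the in-lane target/GAPDH ratio has
  exactly the requested mean and SD given the loading-control
  variability (lognormal ratios are again lognormal, so the algebra is
  exact).

## Statistics conventions

Bin edges follow the printed text exactly, including its asymmetries:
OSI ≤ 0.4 / (0.4, 0.65) / ≥ 0.65; DSI ≤ 0.4 / (0.4, 0.6) / ≥ 0.6;
OR ≤ 60 / > 60; AR < 30 / ≥ 30 (exactly 30 is unassigned in the printed
wording and goes to the upper bin); SA < 5 / [5, 10] / > 10; SNR < 10 /
≥ 10 (10 likewise to the upper bin). Percentages round to one decimal.
The chi-square test is Pearson's without continuity correction. The
t-test defaults to Welch (the usual "Student's t-test" phrasing does not
specify the variance treatment; pooled is a flag), and a one-tailed p is
half the two-tailed p in the hypothesized direction. The two-way ANOVA
requires a balanced design — the simulator produces balanced designs,
and unbalanced input is rejected rather than silently re-weighted; a
one-level second factor degrades to one-way ANOVA, and all-equal data
report F = 0. Percent changes are 100·(comparison − reference)/reference
rounded to one decimal, except the spontaneous-activity change, which is
reported to the nearest integer as printed. Layer assignment uses
half-open depth intervals I [0, 100), II–III [100, 500), IV [500, 700),
V [700, 1100), VI [1100, 1500] µm, with the deepest edge closed.

## Histology quantification conventions

Segmentation is intensity thresholding plus connected components
(EBImage's labelling) with an area filter in µm²; centroids are reported
in calibrated micrometres. Double labelling is decided by greedy
nearest-centroid matching under a 5 µm cap — identical machinery for
point maps and rendered images, which is why centroid distance was
chosen over mask overlap. AOI counting is left/top-edge inclusive so
tiled AOIs count each cell exactly once. Per-AOI GABA⁺/NeuN proportions
(undefined when an AOI has no NeuN⁺ cells; such AOIs are excluded with a
warning) are averaged per group and layer — the mean-of-ratios reading,
consistent with per-layer SDs being reported. Fluorescence intensity
subtracts a background estimated as the mean of the lowest-decile pixels
(a fixed-constant mode exists) and averages per-AOI means on a [0, 1]
scale, matching the magnitude of printed intensity values.

## Problem sizes used by the checks

The package's own validation uses: a 100-point noiseless parameter grid
(θ0 off the sampling lattice, σ ∈ [10°, 16°] where the plug-in baseline
rule is exact to ~10⁻⁵, a2 up to 0.45) refit to parameter errors below
10⁻³; 200 simulated neurons per preset for index recovery (mean
absolute OSI/DSI error below 0.05, fit-filter pass rate above 90%);
an exhaustive family of 2×2 integer tables (cells 1–6) plus random 2×3
tables against a hand-written Pearson oracle, and balanced toy designs
against a from-scratch sum-of-squares decomposition; 100 seeded
replicates for group-separation checks; and 200 AOIs for histology
calibration. These sizes are the package's choices for routine
validation; all are configurable upward.

For the group-separation replicates, the significance bounds mirror what
the source reports per comparison: OSI, SA, and GAD67 fluorescence are
tested at p < 10⁻⁶ (printed as p < 0.000001), the GAD67/GAPDH blot
ratio at the study's α = 0.05 with its n = 6 lanes per group (printed
p = 0.0027; at n = 6, re-simulated data cannot clear a much stricter
bound in ≥ 90% of replicates, which is a power fact about the design,
not about the implementation), and the GAD65 blot — reported as
marginal in the source — is checked for direction only.

## What the generator does and does not emulate

Passing these checks shows that the estimators are correct and
well-calibrated on data generated by the stated stochastic models. Real
recordings and micrographs differ in ways the generator deliberately
omits: per-neuron joint structure (e.g. OSI–SA correlation; fields are
drawn independently), biophysical spike shapes and electrode drift,
eye-dominance and receptive-field structure, anaesthetic state, spatial
clustering of cells and inter-animal variance in histology (published
per-layer SDs include biological variance between slices and animals,
so the generator's Poisson-only SDs are smaller), confocal PSF and
z-stack artefacts, and film-scanning nonlinearity in blots. Published
exact p-values and real-data cell counts are therefore not reproduction
targets — only directions, magnitudes, and significance bounds under
the published moments are.

## Known limitations

The fitting-error filter at 0.5 on normalized curves is permissive: at
the simulated noise levels essentially every neuron passes, so the
filter's selectivity is exercised only by the degenerate-input tests.
The baseline plug-in rule biases wide-curve parameters slightly (see
above). Greedy centroid matching is not globally optimal for dense maps
(an assignment-problem solver would be); at realistic densities and a
5 µm cap the difference does not appear in the planted-truth checks.
The balanced-ANOVA requirement is a deliberate restriction, not a
limitation of the method family.
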