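---
title: "Models and methods behind mbflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mbflex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mbflex` analyses how the fly mushroom body supports flexible recall of an
odor memory: whether Kenyon-cell (KC) population activity can discriminate
two chemically similar odors, how learning-induced depression of a mushroom
body output neuron (MBON) generalizes across them, and how the *order* in
which a fly encounters the two odors at a boundary restores discriminability
— in MBON physiology and in arena behavior. The package implements the
quantification end to end and pairs it with seeded synthetic-data generators
so that every analysis stage can be validated against known ground truth.

Throughout, `A` is the odor paired with reinforcement, `Aprime` a similar
unpaired odor with a strongly overlapping KC representation, and `B` a
dissimilar odor.

## Calcium-trace quantification

Raw ROI fluorescence is processed in a fixed order: the per-field background
(PMT offset plus autofluorescence) is subtracted once
(`subtract_background()`), then per cell and per trial

$$\Delta F/F_i = (F_i - F_0)/F_0,$$

where $F_0$ is the mean fluorescence over an 8 s baseline window on that
same trial, immediately before the first odor onset (`compute_dff()`).
Provenance flags enforce the order (no double subtraction, no subtraction
after ΔF/F) and a non-positive $F_0$ is an error naming the offending
(cell, trial) pairs.

A 0.2 s boxcar filter exists **only** for plotted traces
(`boxcar_filter()`, used by `plot_trace_summary()`); filtered tensors are
flagged and refused by every quantification function. All statistics are
computed from unfiltered ΔF/F.

Quantities derived from ΔF/F:

* **Response amplitude** (`response_amplitude()`): mean ΔF/F over a window
  anchored at an odor-epoch onset; the standard summary window is 8 s from
  onset, and for transition trials the window is anchored at the *second*
  pulse onset. Seconds map to frames by the half-open rule
  $[a, b) \mapsto \lfloor a \cdot \text{rate}\rfloor + 1 \ldots
  \lfloor b \cdot \text{rate}\rfloor$, which keeps adjacent windows disjoint.
* **Transition contrast** (`transition_contrast()`): max ΔF/F during the
  second pulse minus min ΔF/F during the first pulse, signed by default (the
  orientation that assigns large scores to a recovered second response after
  a depressed first one); invariant to adding a constant to the trace.
* **Sorted trial-average heatmaps** (`trial_average_sorted()`): per-stimulus
  trial means with rows ordered by descending amplitude to a chosen sort
  stimulus, stable ties by cell index.
* **Population geometry** (`pca_project()`): trial response vectors
  mean-centered and projected on the top two principal axes; each axis is
  oriented so its largest-magnitude loading is positive, fixing the sign
  ambiguity. Verified against a direct eigen decomposition in the tests.
* **Similar-odor coding overlap** (`odor_response_correlation()`): Pearson
  correlation of per-cell mean amplitudes between two odors, pooled across
  all cells (and flies when present), with a two-sided p-value.

## The logistic population decoder

The decoder asks whether a trial's KC activity vector was evoked by a
particular odor. For an $m \times n$ feature matrix $X$ (trials × cells)
and weights $\theta$ (no intercept — the model is exactly
$h = \sigma(X\theta)$ with one weight per cell):

$$h = \frac{1}{1 + e^{-X\theta}}, \qquad
\text{cost} = -\frac{1}{m}\sum_i \big[y_i \log h_i + (1-y_i)\log(1-h_i)\big]
+ \frac{\lambda}{2m}\sum_j \theta_j^2 .$$

Predictions are clipped to $[10^{-12}, 1-10^{-12}]$ inside the cost to keep
the logs finite. The analytic gradient
$\frac{1}{m}X^\top(h - y) + \frac{\lambda}{m}\theta$ is checked against
central finite differences (< 1e-6 relative) in the test suite.

Fitting (`fit_decoder()`) is deterministic full-batch gradient descent:
initial learning rate 0.1, up to 10,000 iterations, convergence when the
cost improvement falls below 1e-8; a step that would raise the cost is
retried at half the rate, so the accepted cost sequence is non-increasing.
These optimizer constants are package choices — the method is defined by the
cost, not the optimizer — and the tests verify the behavior that matters:
monotone cost, perfect separation on separable data, and weight-norm
shrinkage as λ grows.

Two initializations are provided, matching the two usages: `ones` (all
weights 1, used with λ = 0 by the transfer protocols) and `connectome`
(weights drawn uniformly from synapse counts normalized to the observed
maximum, mimicking the anatomical distribution of KC→MBON synapse weights).
λ = 1 is the default for odor decoding and is not a sensitive parameter.

**Cross-validation** (`loocv_odor_accuracy()`): one-vs-rest targets per
odor, leave-one-out over *all* trials (each fold holds out exactly one trial
and trains on the rest, all classes included). The reported per-odor
accuracy is the hit rate on held-out target-odor trials — the quantity the
per-fly, per-odor accuracy summaries use — with an optional balanced mode
that also scores held-out negatives. A fold whose training set lost a class
is skipped with a warning. A prediction exactly at the 0.5 threshold counts
as positive.

**Transfer protocols** (`protocol_mbon_emulation()`,
`protocol_transition_trained()`): the first trains models to emulate a
depressed MBON — outputs low for `A` and `Aprime`, high for `B` — on
isolated-pulse trials only (λ = 0, weights initialized at 1), then evaluates
the held-out pulse and all transition trials per fold. The second re-trains
with the transitions added to the training set, targets A′→A = 0 and
A→A′ = 1, demanding order-selective output. When transition features carry
no order information (`order_effect_eps = 0` in the generator), A→A′
features are distributed exactly like A′ pulse features but carry the
opposite target, so no model can satisfy both — the dissociation is
provably unattainable, and the tests assert exactly that. With a
sufficiently large order perturbation (found by a pilot sweep in the
acceptance tests), the trained models place A→A′ above threshold and
A′→A below it while keeping both pulse outputs low.
`weight_response_correlation()` confirms that weights trained to silence
`A` end up negatively correlated with per-cell `A` responses.

## Arena behavior

`quadrant_counts()` counts centroids per quadrant per frame; quadrant $q$
spans polar angles $[(q-1)\cdot 90°, q\cdot 90°)$ about the arena center,
so a fly exactly on a boundary belongs to the counter-clockwise-adjacent
quadrant (deterministic, measure-zero choice; rotating all positions by 90°
permutes counts cyclically).

The performance index is
$\mathrm{PI}(t) = (N_\text{paired} - N_\text{unpaired})/N_\text{total}$,
summarized as the mean over the final 30 s of the test period, frames in
$[T_{end} - 30\,\mathrm{s}, T_{end})$ (`performance_index_series()`).
Discrimination designs average two reciprocally trained groups
(`reciprocal_pi()`); generalization designs, which cannot be reciprocal,
subtract an unpaired control after correcting both PIs by their pre-odor
baselines (`generalization_score()`).

Upwind displacement is $d_i(t) = r_i(t) - r_i(\text{onset})$, the change in
distance from the arena center (odor flows inward from the rim, so upwind is
outward), averaged across the flies of an arena and summarized as the mean
of the arena series over the stimulus window (`upwind_displacement()`).
`radial_position_at()` supplies the starting-position control for
cross-condition comparisons. Flies with missing frames are dropped, not
interpolated.

## Statistics

Group comparisons use the two-sided independent-sample Wilcoxon rank-sum
test (PIs across treatment groups) and the paired Wilcoxon signed-rank test,
with Bonferroni–Holm correction within explicitly declared families
(`independent_rank_sum()`, `paired_signed_rank()`, `holm_correction()`,
`adjust_families()`). Exact null distributions are used for group sizes up
to 8 (tests verify the exact p for complete separation at 6 vs 6,
$2/\binom{12}{6}$, against an explicit enumeration); larger samples use the
normal approximation with continuity correction. All-zero paired
differences are an error rather than a degenerate p-value. The correction
is delegated to `stats::p.adjust` behind the package surface and checked
against a hand-written step-down oracle. Summary figures use mean ± SEM
with SEM = SD/√n (`sem()`).

## Synthetic study conditions

The generators produce data with the statistical structure the analyses
assume, at the study's scales, and return the latent parameters they used.

**KC datasets** (`gen_kc_dataset()`): 8 repeats per stimulus of three single
pulses and both transitions, at 10 Hz. Defaults: 500 cells, responder
fraction 0.1 (sparse coding), A–A′ responder overlap 0.8, A–B overlap 0.05,
and a *population-level* per-cell amplitude correlation target of 0.74 for
the similar pair — the γ-KC value; the within-shared-responder latent
correlation needed to realize it is solved in closed form from the responder
fraction, overlap, and amplitude moments, and infeasible combinations raise
an error instead of silently missing the target. Amplitudes are Gaussian
around 1.0 ΔF/F (SD 0.3); traces use a double-exponential rise/decay
(0.3 s / 1 s); per-frame Gaussian noise, SD 0.05 ΔF/F. Pulses last 5 s
(the isolated-pulse duration is a free design parameter; it is configurable
and nothing downstream depends on it) after an 8 s baseline. In transition
trials the first-pulse response terminates at the handoff, so the
second-pulse window reflects the second odor alone — this makes the
construction exact: second-pulse response = that odor's single-pulse
response + `order_effect_eps` × an order-signed perturbation carried by a
random 20% cell subset (+ for A→A′, − for A′→A). Raw fluorescence is
synthesized as $F = \text{background} + F_0(1 + \Delta F/F)$ so the full
background/ΔF/F pipeline is exercised.

**MBON datasets** (`gen_mbon_dataset()`): a single ROI over the six-stimulus
schedule (three pulses, both similar-odor transitions, a B-containing
control transition). Post-pairing amplitudes scale the pre-pairing ones:
0.3 for isolated `A` and `Aprime` (strong depression that generalizes
across the similar pair), 1.0 for `B`, and — the order asymmetry — the
second pulse of A→A′ recovers by `transition_recovery` (default 1.0) while
a second `A` or a B-preceded `Aprime` stays depressed.

**Synapse counts** (`gen_synapse_counts()`): lognormal counts rounded to
integers ≥ 1, mean 2959/336 ≈ 8.8 synapses per KC, matching the anatomy of
a compartment receiving 2,959 synapses from 336 KCs.

**Arena trajectories** (`gen_arena_trajectories()`): 15 flies per arena in
a 50 mm-radius disk, tracked at 5 Hz, independent Gaussian steps of SD 4 mm
per frame (≈ 20 mm/s of walking) with radial reflection at the wall. Flies
start uniform over the disk — the stationary distribution of the unbiased
walk — so unstimulated epochs carry no systematic radial trend. During
odor-pulse epochs an outward drift of `upwind_drift` mm/s is added; during
choice-test epochs a Metropolis acceptance rule gives the favored (paired
odor) quadrants a stationary occupancy density `quadrant_bias` times that of
the disfavored ones, so the stationary favored:disfavored ratio equals the
bias and the stationary PI is $(b-1)/(b+1)$.

Two measurement subtleties are worth recording. First, the reflecting wall
partially cancels outward drift: a proposal that crosses the wall is folded
back, flipping its drift component, which removes a substantial fraction of
the planted drift from naïve increment averages at the default step size —
and once stimulated and control trajectories diverge, the curvature of the
radial coordinate ($\mathbb{E}[\Delta r \mid r] \approx \sigma^2/2r$ for a
2-D walk) biases their difference. `estimate_upwind_drift()` therefore
compares paired runs generated with common random numbers, uses only the
first second after onset (before the pair diverges), and restricts to a
10–40 mm annulus; the tests verify recovery of planted drifts within the
±10% tolerance they state. Second, the
Metropolis chain relaxes toward its biased stationary state on the
diffusion timescale $L^2/\pi^2 D \approx 25$ s at the defaults, so a 60 s
choice test summarized over its last 30 s slightly underestimates the
stationary PI; the planted-bias recovery is still within ±0.1 PI units at
15 flies × 12 runs, the tolerance used by the tests.

## What the synthetic conditions do and do not show

The generators emulate the *statistical* structure the analyses rely on:
sparse overlapping codes with a controlled amplitude correlation,
order-dependent transition information, order-asymmetric MBON depression,
and stimulus-conditioned locomotor biases. They do not model biophysics
(no KC thresholding dynamics, no adaptation, no plasticity rule), noise is
additive Gaussian rather than photon-limited and correlated, locomotion is
a memoryless random walk rather than runs and turns, and trial-to-trial
response variability has no structure across cells. Green tests therefore
certify that the *pipeline* recovers what it is supposed to recover under
controlled conditions — not that real recordings satisfy those conditions.

## Problem sizes and reproducibility

The test suite and acceptance script use the study's scales where they are
the point (500 cells, 8 trials per stimulus, 15 flies per arena; the
transfer protocols use 120-cell populations, in the range of per-fly model
sizes) and smaller populations for structural unit tests. Every stochastic
stage takes an explicit seed; `run_config()` derives per-stage seeds from
one global seed, and a stored config reproduces all outputs bit-identically
(`run_all()`, verified in the tests). The fully-worked pipeline is:

```{r example}
library(mbflex)
run <- run_all(run_config(seed = 1), out_dir = "mbflex-demo")
run$results
```
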