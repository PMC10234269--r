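---
title: "Foot placement errors and push-off kinetics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Foot placement errors and push-off kinetics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitfpe)
```

## The scientific question

During steady-state walking, anterior–posterior (AP) foot placement covaries
with the state of the body's center of mass (CoM): where the foot lands can be
predicted, to a substantial degree, from the CoM AP position (relative to the
stance foot) and velocity during the preceding swing. If that covariance
reflects a control strategy, the *residual* of the prediction — the **foot
placement error** — is a deviation the walker should want to correct. A
natural corrective channel is ankle push-off: a foot placed further forward
than predicted lengthens the step, increases the collision loss at contact,
and calls for a stronger push-off by the trailing leg during the subsequent
double stance.

`gaitfpe` implements the full analysis chain for this question on treadmill
gait data, plus a synthetic generator that embodies the assumed generative
structure so every stage can be validated against ground truth.

## The models

**Foot placement model.** For step $i$ (heel strike to contralateral heel
strike, phase $j \in [0, 100]\%$), with all variables de-meaned per
participant, foot and condition,

$$\mathrm{FP}_i(j{=}100\%) = \beta_{\mathrm{pos}}(j)\,
\mathrm{CoM}_{\mathrm{pos},i}(j) + \beta_{\mathrm{vel}}(j)\,
\mathrm{CoM}_{\mathrm{vel},i}(j) + \varepsilon_{\mathrm{FP},i}(j),$$

fitted by independent two-predictor, zero-intercept OLS at every phase sample
(`fit_fpm()`). De-meaning the outcome *and* both predictors makes the zero
intercept exact and forces the residual mean to zero at every phase — a
property the tests assert to $10^{-10}$. $R^2(j)$, coefficient curves,
per-phase F tests (2 and $n-3$ degrees of freedom; the de-meaning absorbs
one) and the residual matrix are returned. The **foot placement error** is
the residual at $j = 100\%$: positive means the foot landed further forward
than the linear prediction.

**Correction model.** The error of step $i$ is then related to kinetic time
series $F$ of the subsequent step,

$$F_{i+1}(j) = \beta_{\varepsilon\mathrm{FP}}(j)\,
\varepsilon_{\mathrm{FP},i}(j{=}100\%) + \varepsilon_{i+1}(j),$$

for three signals: the combined AP ground reaction force (GRF), the trailing
leg's AP GRF, and the trailing leg's sagittal (plantar-flexion positive)
ankle moment. Because push-off can begin before contralateral heel strike,
the analysis covers the *complete stride*: the same-step series $F_i(j)$
spliced to the next-step series $F_{i+1}(j)$ at the heel strike where the
error is evaluated (`pushoff_correlation_field()`). The headline quantity is
the phase-wise Pearson correlation $r(j)$; the regression slope is retained
alongside since, with one predictor, the two are monotonically related.
Phases where a per-leg signal is identically zero (the trailing leg's swing)
are masked rather than reported as spurious zeros. In addition,
`extreme_error_contrast()` mirrors the tail comparison: the mean kinetic
curves of the $k = 10$ most positive versus most negative error steps.

**Group inference.** Per-participant curves (the Fisher-z average of the two
per-foot fields, so the participant stays the independent unit) are
aggregated with the r-to-z transform — average in $z = \operatorname{atanh}(r)$
space, back-transform with $\tanh$ (`fisher_mean()`) — and tested against
zero with one-dimensional cluster inference: the pointwise $t$ field is
thresholded at the two-sided $t$ critical value for $\alpha = 0.05$,
contiguous supra-threshold runs form clusters scored by their summed $|t|$,
and cluster p-values come from the null distribution of the *maximum*
cluster score over sign-flip permutations
(`permutation_cluster_inference()`). This respects the smoothness of the
phase axis: a cluster must be large or sustained to be significant.

### Why permutation rather than parametric 1D thresholds

Random-field-theory thresholds (the parametric route taken by SPM-style
toolboxes) need smoothness estimation and distributional assumptions.
Sign-flip permutation needs only per-participant sign symmetry under the
null, is assumption-light, and — crucially for this package — is *exactly
testable by simulation*: the test suite runs hundreds of replicate null
experiments and checks that the family-wise false-positive rate matches the
nominal level within binomial error. When the number of distinct sign
patterns does not exceed the requested permutations, the distribution is
enumerated exhaustively. The identical hypotheses are tested; only the
thresholding machinery differs.

## The synthetic generator

`simulate_trial()` produces a full multichannel trial in the lab (treadmill)
frame; `simulate_step_data()` is the step-level fast path that draws the
same step-to-step quantities directly on the phase grid (used for large-n
convergence and calibration studies where synthesizing and re-detecting
continuous signals adds nothing but runtime).

Generative structure, per step $i$:

1. Heel-strike CoM states $(p_i, v_i)$ follow a stationary 2-D linear
   step-to-step map (spectral radius < 1) around configurable means.
2. $\mathrm{FP}_i = \beta_{\mathrm{pos}} p_i + \beta_{\mathrm{vel}} v_i +
   \varepsilon_i$, $\varepsilon_i \sim \mathcal N(0, \sigma_{\mathrm{fp}}^2)$
   exactly Gaussian.
3. Within-step CoM trajectories are $C^1$ cubic Hermite interpolations
   consistent with the drawn heel-strike states; heel trajectories drift
   backwards at belt speed in stance and swing forward smoothly.
4. Each leg's stance kinetics are a smooth baseline profile (braking →
   propulsive AP GRF lobe; late-peaking plantar-flexion moment) plus smooth
   Gaussian noise (configurable FWHM, default 10% of a step, so smoothness
   estimation has a known target) plus, over the leg's final double stance,
   a gain profile times $\varepsilon_i$ — the generative mirror of the
   correction model. Per-leg kinetics are exactly zero in swing.
5. The combined CoP dwells under the stance foot (drifting backwards at belt
   speed, progressing heel-to-toe) and transfers mediolaterally to the other
   foot linearly over each double stance — the "butterfly" whose kinks at
   transfer onset/completion are the heel-strike and toe-off signatures the
   detector uses.

Everything is deterministic given the seed, and all truth (events, states,
errors) is retained.

Because the analytic within-step state propagation used for reference
curves (`true_state_matrices()`, `fpm_true_coefficients()`) is a linear,
invertible map of the heel-strike state, a foot placement vector built
exactly from the states is recovered by `fit_fpm()` with zero residual and
the implied coefficient curves at *every* phase — the package's strongest
correctness anchor, asserted to $10^{-10}$.

For any kinetic signal the generator also yields a closed-form correlation
target,
$$r^*(j) = \frac{g(j)\,\sigma_{\mathrm{fp}}}
{\sqrt{g(j)^2 \sigma_{\mathrm{fp}}^2 + \sigma_\eta^2}},$$
(`expected_correlation_profile()`; the combined GRF carries both legs'
noise during double stance, doubling $\sigma_\eta^2$ there). Estimated
fields converge to this curve in sup-norm as $1/\sqrt{n}$; the acceptance
suite checks sup-norm < 0.02 at 20,000 strides.

### Default parameters and why

| parameter | normal | slow | rationale |
|---|---|---|---|
| belt speed | $0.4\sqrt{g l}$ | $0.2\sqrt{g l}$ | constant dimensionless speed; leg length 0.9 m |
| `n_strides` | 200 | 200 | length of the analyzed steady-state record |
| `step_time` (s) | 0.60 | 0.75 | metronome-paced cadence, slower gait at the lower speed |
| `ds_fraction` | 0.20 | 0.25 | relative double stance grows as speed drops |
| `beta_pos`, `beta_vel` (–, s) | 0.6, 0.25 | 0.6, 0.25 | velocity contributes more predicted variance than position |
| `sigma_fp` (m) | 0.008 | 0.011 | yields heel-strike $R^2 \approx 0.70 / 0.55$, inside the 50–80% range typical of treadmill data; slow-walking errors are more variable |
| `gain_grf` (N/m) | 450 | 290 | peak double-stance correlation ≈ 0.45 / 0.41 for the trailing AP GRF |
| `gain_moment` (N·m/m) | 220 | 150 | peak ≈ 0.40 / 0.38 for the ankle moment; combined GRF then peaks ≈ 0.34 / 0.31 by noise pooling |
| `sigma_eta_grf`, `sigma_eta_moment` | 7 N, 4 N·m | same | stride-to-stride kinetic variability at fixed phase |
| gain shape | skewed Hann | same | zero at both double-stance edges, peak ≈ 2/3 in (≈ 80 ms after heel strike at normal speed) |
| `noise_fwhm` (% step) | 10 | 10 | smooth, band-limited measurement noise |
| `sigma_cop` (m) | 0.002 | 0.002 | CoP noise, 4% of the ML butterfly amplitude |
| `step_width` (m) | 0.10 | 0.10 | ML distance between feet (butterfly peak-to-peak) |

These were chosen once, from the effect sizes and study dimensions typical
of steady-state treadmill experiments, and are not tuned thereafter. A
`"flat"` gain shape (strictly positive across the whole double stance) is
available for studies of sign properties where a gain vanishing at the
window edges would make edge phases uninformative coin flips.

### What the generator does *not* emulate

No musculoskeletal or forward dynamics: kinetic shapes are stylized
profiles, not the output of a pendulum walker. CoM velocity is exactly the
derivative of the CoM trajectory only within steps (states are drawn, not
integrated through collisions). Real data add soft-tissue artifacts,
marker noise, asymmetries, drifts and non-Gaussian error tails; passing
tests therefore demonstrate the *pipeline's* correctness under the stated
model, not that real gait satisfies the model.

## Event detection

The cited CoP-butterfly method is not spelled out in the motor-control
literature at implementation level; the committed interpretation here is:

1. smooth the ML CoP (Gaussian, default 30 ms FWHM) and locate transfers as
   hysteresis crossings of the midline between the two plateau levels —
   alternating by construction and free of any physical-unit threshold;
   crossing pairs closer than `min_step_time` are discarded as noise
   toggles;
2. place coarse edges half a transfer-width either side of each crossing,
   the width estimated from the plateau separation and the median mid-ramp
   slope;
3. sharpen each edge to the slope discontinuity of the *raw* ML signal —
   the local maximum of the fourth difference, which is essentially
   noise-free for smooth (band-limited) measurement noise — with a joint
   pass that exploits the fixed double-stance duration within a condition
   by scoring edge pairs at the consensus spacing.

On synthetic trials the detector recovers ≥ 99% of events within ±1 sample
at 200 Hz for noise up to 20% of the ML butterfly amplitude (half the
peak-to-peak excursion), and still ≈ 96% at double that noise. Transfers
touching the trial boundaries are undetectable in principle and skipped.
Validation is against synthetic truth only; real-data validation is out of
scope.

## Normalization choices

Steps are time-normalized in two independent sub-windows — double stance to
`J_ds` samples, single stance to `J_ss` (defaults 20/80 normal, 25/75 slow)
— so that the contralateral heel strike is always exactly phase 100% and
double-stance phases are aligned across steps despite timing variability.
Fixed *sample counts* (rather than fixed absolute sub-window durations) are
the default because they give every step the same grid within a condition;
original durations are preserved in the metadata. Interpolation is linear
by default: exact on constants and ramps, monotone, and free of overshoot
at kinetic transients; a cubic option exists. Boundary steps lacking a
following step are kept through segmentation and excluded only where the
correction model needs index $i+1$.

## Numerical and degenerate-input policy

* OLS at each phase via closed-form normal equations with an explicit
  rank-deficiency flag (`NA` coefficients, never silent zeros).
* Zero-variance errors (e.g. `sigma_fp = 0`) raise explicit errors in
  correlation routines rather than propagating `NaN`.
* Correlations with $|r| \ge 1$ are clipped to $1 - 10^{-12}$ with a warning
  before the z transform.
* Masked phases break cluster contiguity; clusters never span a mask.
* Permutation tests require an explicit seed; with few participants the
  sign patterns are enumerated exhaustively (with a message).
* Monte-Carlo p-values use $(1 + \#\{T_b \ge T_{\mathrm{obs}}\})/(B+1)$,
  which is valid (never anti-conservative) at finite $B$.

## Problem sizes used in the shipped studies

The package's own studies (test suite and acceptance script) use: exact
identities on 50-stride trials; coefficient-recovery RMSE at 50/200/800
strides with 100 replicates (log–log slope $-0.5 \pm 0.1$);
correlation-field convergence at 20,000 strides (sup-norm < 0.02); detection
sweeps at 200 strides and 200 Hz; tail contrasts with $k = 10$ of 200
strides, 100 replicates; and the null calibration with 200 replicate
experiments of 20 synthetic participants, 1,000 permutations each, via the
step-level fast path. These sizes make each study reproducible on a single
CPU in minutes while keeping Monte-Carlo error well below the tolerances
tested.

## Known limitations

* The correlational design cannot separate feedback control from passive
  dynamics or intrinsic muscle properties; the generator *builds in* a
  feedback gain, so recovering it validates estimation, not mechanism.
* Mediolateral foot placement, ankle power/work/impulse outcomes, and
  marker-based event detection are out of scope.
* The per-foot curves of one participant are averaged in z-space before
  group testing; treating feet as independent samples would roughly double
  the apparent sample size and is deliberately avoided.
* Real CoM velocity may or may not include belt speed depending on the
  measurement frame; after de-meaning this does not affect slopes, but
  adapters for recorded data should note the frame in metadata.
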