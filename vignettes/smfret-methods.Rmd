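---
title: "Models and methods behind smfret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smfret}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smfret)
```

# Scope

smfret quantifies protein–DNA kinetics from two-color single-molecule FRET
trajectories of surface-tethered DNA, for two experimental designs:

1. **Unwinding snapshots.** Short movies taken at a series of timepoints
   after adding an unwinding enzyme (dCas9–gRNA). Each molecule contributes a
   few FRET values to a population histogram; the histogram is decomposed
   into three Gaussian populations (a donor-only artifact peak plus wound and
   unwound signal peaks); the unwound fraction is followed over time and
   fitted to a one-phase association law.
2. **Binding movies.** Long continuous movies of a labeled protein (MutS)
   binding a mismatch on acceptor-labeled DNA. Binding events appear as
   intensity bursts with a high-FRET specifically-bound level that either
   ends in dissociation or converts to a low-FRET sliding-clamp level.
   Dwell-time survival analysis and branch counting turn these into rate
   constants.

Both pipelines are exercised end to end against a seeded synthetic-trace
generator, so every estimator in the package is validated by parameter
recovery: simulate with known rates, analyze blind, compare.

# The generative model

## State dynamics

Molecular states evolve as a continuous-time Markov chain realized by the
Gillespie algorithm (`simulate_ctmc_path()`). The two-state scheme has
wound ⇄ unwound transitions with rates `k_unwind`, `k_rewind`. The binding
scheme has dark → bound arrivals at `k_arrival` (pseudo-first-order at the
experiment's fixed protein concentration), bound → dark at `k_dissoc`,
bound → clamp at `k_clamp`, and clamp → dark at `clamp_exit`. Sojourns are
exponential with the total exit rate; exits branch in proportion to the
rates, so the clamp branch probability is `k_clamp / (k_dissoc + k_clamp)`.

## Trace rendering

`render_trace()` samples the state at each frame midpoint and splits a
constant total intensity between channels by the state's FRET efficiency,
drawn per frame from the state's Gaussian emission: acceptor
`= background + E * total`, donor `= background + (1 - E) * total`. Direct
acceptor-excitation frames report acceptor presence. Defaults are Gaussian
read noise per channel (`intensity_sd = 30` on a total of 1000, background
50) — values chosen for clear but not trivial state separation, since the
source experiments report no camera model; Poisson (shot-noise) rendering is
available via `noise_model(shot_noise = TRUE)`. Photophysics covers
single-step donor/acceptor bleaching, a configurable fraction of molecules
with an inactive acceptor (the population the acceptor-presence filter
removes), and an unlabeled fraction.

Default movie layouts mirror the source experiments: 10 donor + 10 acceptor
excitation frames at 50 ms for snapshots; 10 acceptor + 980 donor + 10
acceptor frames at 200 ms for binding movies with ADP; 10 + 1480 + 10 at
50 ms for ATP.

## Snapshot quasi-statics

Snapshot experiments image a field for ~20 s at minute-scale intervals, so
the generator draws each molecule's state at the sampling instant
(unwound with probability `y0 + (plateau - y0)(1 - exp(-k t))`) rather than
simulating a full trajectory between timepoints. Each molecule contributes
five histogram values drawn from its component's Gaussian. A configurable
donor-only weight (default 0.10) populates the artifact peak. Mono/di-label
heterogeneity of the protein dye is not modeled by default; it can be
emulated by widening `fret_specific`.

## Reproducibility

One master seed per `sim_config()`; per-molecule (or per-timepoint) streams
are derived deterministically from it, so identical configs give
bit-identical datasets, which the test suite asserts at the file level.

# Analysis methods

## FRET and filtering

FRET is computed as the background-corrected proximity ratio
`E = (IA - bA) / ((IA - bA) + gamma (ID - bD))` with `gamma = 1` by default;
the source histograms span 0–1 and no detection-correction factor is
reported, so gamma is exposed but not applied. Frames with non-positive
corrected total give `NA` rather than an error. Molecules whose median
acceptor intensity under direct excitation does not exceed background plus a
margin are dropped. Histograms use each molecule's 3rd–7th donor-excitation
frames (1-based ordinals), the window that avoids both the first frames
(shutter/settling) and later frames (bleaching).

## Population decomposition

`fit_three_gaussians()` fits the binned density (bin width 0.02 FRET units)
with a weighted sum of three Gaussians by nonlinear least squares
(Levenberg–Marquardt), matching the histogram-fitting procedure of the
source analysis rather than a raw-sample EM. Component sds are floored at
0.005 to forbid spike components; starting means come from the 10/50/90th
percentiles. Classification thresholds are the intersection points of
adjacent fitted components, solved in closed form as a quadratic in `x`;
when no root lies between two means (one component dominates), the
sd-weighted midpoint is used and flagged. The fixed windows 0.14–0.47
(PAM-proximal geometry) and 0.18–0.51 (PAM-distal) are provided as
ready-made rules for reproduction runs; intersection-derived thresholds are
the default for new data. Threshold comparisons are strict, so a value
exactly at a boundary is outside the unwound window, and values at or below
the lower threshold (donor-only peak) are excluded from the molecule total.

For time courses, the package fits one pooled mixture across all timepoints
and applies its thresholds everywhere (`fraction_unwound_timecourse()`
default). The populations only shift weight over time while the peak
positions stay put, and pooling avoids the unstable early-timepoint fits
where one signal component is nearly empty; a per-timepoint option exists.
Note that with thresholds fixed across time, constant misclassification
rates act as a fixed linear transform of the true fraction, which biases
`y0`/`plateau` slightly but leaves the rate constant `k` untouched.

## One-phase association fit

`fit_one_phase_association()` estimates `(y0, plateau, k)` in
`y = y0 + (plateau - y0)(1 - exp(-k t))` by weighted nonlinear least squares
(inverse-binomial-variance weights when counts are available). Time is in
minutes and `k` in min⁻¹ (summaries carry the s⁻¹ conversion). Parameters
are bounded only by loose sanity limits ([-0.2, 1.2] for the fractions) to
tolerate boundary noise without wedging the optimizer. All timepoints enter
the fit; plotting can trim late points for display only
(`autoplot(fit, trim_after = 20)`). A constant series returns
`plateau = y0` with `k` flagged unidentifiable; a decreasing series fits
normally and is flagged by `direction`.

## Idealization and dwells

`hmm_idealize()` fits a per-trace Gaussian-emission hidden Markov model by
maximum likelihood (Baum–Welch, ≤ 500 iterations, log-likelihood tolerance
1e-6) and decodes with Viterbi. Initialization is deterministic (state means
at the 25/75th percentiles, shared variance, uniform transitions), so
idealization is reproducible; states are relabeled by increasing emission
mean. This replaces interactive/variational tooling with a reproducible
maximum-likelihood equivalent, and `threshold_idealize()` provides the
transparent cross-check: on well-separated emissions the two agree on
> 98% of frames. Dwells are maximal constant-state runs; the first and last
run of every trace are marked censored and excluded from all rate fits. The
censoring policy matters: when the mean dwell is no longer small relative to
the observation window, completed dwells are biased short and uncensored-only
rate estimates biased high — the package's tests assert this bias
directionally, and the recovery experiments below size their windows to
avoid it.

## Event segmentation

`segment_binding_events()` finds binding events as runs of
background-subtracted total intensity above a threshold (which must be
positive — a threshold at or below background would detect noise). Within an
event, frames split at `fret_split` (by default the two-Gaussian
intersection of the pooled event-frame FRET histogram) into the high-FRET
specific-binding level and the low-FRET clamp level. The specific-binding
dwell `t_sb` is the initial contiguous high run; a clamp call requires ≥ 3
consecutive low frames, suppressing single-frame noise artifacts. An event
is censored when its outcome is unknowable: bound at the first frame, high
segment truncated by the movie end, or an ambiguous 1–2-frame low tail at
the end. A clamp already established by 3 low frames stays uncensored even
if the clamp sojourn itself is truncated — censoring by outcome keeps the
branch counts unbiased, whereas censoring every end-truncated event would
preferentially discard clamps.

## Rates

Dwell survival uses the `1 - i/n` convention (the curve reaches zero) and
`fit_single_exponential()` fits `y = y0 + A1 exp(-k t)` with a free offset,
matching the stated 1-CDF procedure; `fit_exponential_mle()` (`1/mean`)
serves as an independent cross-check and the two agree within 3% on clean
simulations. The composite bound-state exit rate decomposes exactly by
branch counts: `k2 = k N2/(N2 + N-1)`, `k-1 = k N-1/(N2 + N-1)`; standard
errors propagate by the delta method from the fit error on `k` and the
binomial branch error. Arrival rates are events per molecule-second.

# Numerical choices and degenerate inputs

* All three nonlinear fits use `minpack.lm::nlsLM` with analytic-free
  Levenberg–Marquardt, ≤ 500 iterations, and explicit failure conditions
  (`smfret_fit_failure`) rather than silent misconvergence.
* Zero-variance FRET histograms, < 100 histogram values, < 10 dwells, empty
  branch counts, or a zero classification denominator raise typed errors.
* Equal-mean Gaussian components have no separating intersection and are
  rejected; coincident-mean mixture fits are reported as failures.
* Ties at classification thresholds fall outside the unwound window
  (strict inequalities).
* The EM sd floor is 1e-4 (FRET units) and emission densities are floored at
  1e-300 to keep the forward pass finite.

# Recovery experiments and their sizes

The acceptance script (`scripts/acceptance.R`) re-derives the headline
quantities by full-pipeline parameter recovery at these problem sizes,
chosen so each estimate's sampling error sits well inside the comparison
tolerance:

* **Dissociation rates** (0.204, 0.107, 0.075 s⁻¹): 5 seeds × 300 molecules
  of ADP-archetype movies, ≥ 2000 uncensored events per seed. These runs use
  an extended acquisition of 3920 donor-excitation frames (784 s) so that
  even the slowest rate's mean dwell (13.3 s) stays below 2% of the window;
  at the default 196 s ADP movie length the uncensored-dwell estimator is
  in its documented bias regime for that rate (+8–15%), which is a property
  of the design, not the estimator. Per-seed recovery there is unbiased
  within ~2%.
* **Equilibrium unwound fractions** (0.77, 0.45): 3 replicates × 5000
  molecules × 5 values, full mixture-fit + intersection-threshold
  classification.
* **Time-course plateaus** (0.79, 0.50; y0 = 0.35, k = 0.3 min⁻¹): 15
  replicate experiments of 5000 molecules per timepoint on the grid
  1–60 min, per-timepoint fractions averaged across replicates before one
  association fit. A single experiment determines the plateau to ±0.01 but
  `k` only to ~16% (plateau 0.50 leaves a 0.15 amplitude over binomial
  noise), so replicate averaging — as in the source study's n = 3–4
  replicate errors — is required for a meaningful rate comparison.

# What the generator does not emulate

Synthetic traces have stationary backgrounds, no donor leakage or direct
acceptor excitation crosstalk during FRET frames, no spatial/diffusive model
of the sliding clamp (a single exit rate), no intensity drift, blinking, or
multi-step bleaching, and Gaussian state emissions without the broad tails
real dye photophysics produce. Passing recovery tests therefore demonstrates
the correctness and calibration of the estimators under the stated model,
not robustness to every optical artifact of real data; the filtering and
threshold parameters are exposed so real datasets can be tuned.

# Known limitations

* Dwells shorter than one frame are invisible; events whose bound dwell
  never spans a frame midpoint are dropped (symmetrically across branches).
* The least-squares survival fit is slightly above the MLE on
  frame-quantized dwells (~2% at 200 ms frames and k ≈ 0.2 s⁻¹); both are
  reported and the discrepancy is far inside the comparison tolerances.
* The per-trace HMM assumes two (optionally three) Gaussian states with
  homogeneous emissions; traces mixing mono- and di-labeled proteins
  violate this and are better segmented with the intensity/threshold rules.
* `fraction_unwound()` treats values, not molecules, as the counting unit;
  with five correlated values per molecule the effective sample size for
  error bars is the molecule count.
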