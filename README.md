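# smfret

Kinetic analysis of two-color single-molecule FRET trajectories of
protein–DNA interactions, with a matched synthetic-trace generator for
end-to-end validation.

## The problem

Surface-tethered, dye-labeled DNA imaged by single-molecule TIRF reports
protein-induced conformational changes as shifts in FRET efficiency between
a donor and an acceptor dye. Two recurring designs:

* **Unwinding snapshots** — a nuclease-dead Cas9–gRNA complex unwinds its
  target; wound and unwound DNA give distinct FRET populations. Short
  movies at a series of timepoints yield FRET histograms whose unwound
  fraction *f*<sub>unwound</sub> grows by one-phase association,
  *y* = *y*₀ + (plateau − *y*₀)(1 − e<sup>−*k t*</sup>).
* **Binding movies** — a dye-labeled mismatch-repair sensor (MutS) binds a
  mismatch (high FRET, dwell *t*<sub>SB</sub>) and either dissociates or
  converts to a low-FRET sliding clamp. Dwell-time survival curves
  (1 − CDF) fit a single exponential *y* = *y*₀ + *A*₁e<sup>−*k t*</sup>
  whose rate is a composite, *k* = *k*₋₁ + *k*₂; the branch counts
  *N*₂/*N*₋₁ = *k*₂/*k*₋₁ split it into dissociation (*k*₋₁) and
  clamp-formation (*k*₂) rates. Arrival counting gives the
  pseudo-first-order binding rate *k*₁.

smfret implements the full chain for both designs — FRET computation and
molecule filtering, three-Gaussian histogram decomposition with
intersection thresholds, one-phase association fits, per-trace
maximum-likelihood two-state HMM idealization, event segmentation with
censoring, survival fits, and the exact branch-ratio decomposition —
plus a seeded generator of synthetic donor/acceptor movies for both
archetypes, so every estimator is validated by parameter recovery.

## Worked example

Simulate dissociation-only (ADP-condition) mismatch-binding movies at the
relaxed-circular dissociation rate, then recover the rate blind:

```r
library(smfret)

kin <- binding_kinetics(k_arrival = 0.0125, k_dissoc = 0.204, k_clamp = 0)
cfg <- sim_config(kin, n_molecules = 200, seed = 42,
                  condition = "relaxed circular + ADP")
movies <- simulate_binding_experiment(cfg)
movies
#> <trace_set> 200 molecules x 1000 frames (200 ms frames), condition 'relaxed circular + ADP'

events <- segment_binding_events(movies$traces, intensity_threshold = 300,
                                 fret_split = 0.55, background = 50)
nrow(events)          # detected binding events
#> [1] 441
sum(!events$censored) # events with a measurable, uncensored bound dwell
#> [1] 426

fit <- fit_single_exponential(one_minus_cdf(events$t_sb[!events$censored]))
fit
#> <exp_fit> y = y0 + A1 exp(-k t): k = 0.1966 +/- 0.0011 s^-1 (n = 426)
```

426 uncensored dwells from a 200-molecule experiment recover the generative
0.204 s⁻¹ to 4%; `glance(fit)` also reports the mean dwell (5.1 s) and
residual. `autoplot(fit)` overlays the survival points and the fitted
exponential. The same pattern drives the snapshot pipeline:
`simulate_snapshot_experiment()` → `fit_three_gaussians()` /
`fraction_unwound_timecourse()` → `fit_one_phase_association()`.

Config-driven runs (simulate / analyze / recover modes with CSV + JSON
outputs and a provenance record) are available through `run_pipeline()` or
the command-line wrapper `inst/scripts/smfret-run.R`.

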