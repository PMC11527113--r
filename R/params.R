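#' Kinetic parameter sets for the synthetic-trace generator
#'
#' Three generative archetypes cover the experiments the package analyses:
#'
#' * `two_state_kinetics()` — reversible wound/unwound interconversion of the
#'   protospacer observed as two FRET levels (continuous dCas9 movies).
#'   `k_unwind` and `k_rewind` are the unwinding and rewinding rate constants
#'   (the kinetic scheme's k1 and k-1, in s^-1).
#' * `snapshot_kinetics()` — quasi-static snapshot sampling of the unwound
#'   fraction, which relaxes toward `plateau` from `y0` by one-phase
#'   association with rate `k_assoc` (min^-1). FRET values are drawn from a
#'   three-component Gaussian mixture: a donor-only artifact peak plus the
#'   unwound (low-FRET) and wound (high-FRET) signal peaks.
#' * `binding_kinetics()` — repeated protein binding at a mismatch: Poisson
#'   arrivals at `k_arrival` per molecule, a high-FRET specifically-bound
#'   dwell with total exit rate `k_dissoc + k_clamp` that branches into
#'   dissociation (probability `k_dissoc / (k_dissoc + k_clamp)`) or a
#'   low-FRET sliding-clamp state that leaves the field of view at
#'   `clamp_exit` (all rates s^-1). `k_clamp = 0` reproduces the ADP-only
#'   condition where no clamps form.
#'
#' @param k_unwind,k_rewind Two-state interconversion rates, s^-1.
#' @param fret_wound,fret_unwound,fret_specific,fret_clamp Length-2 numeric
#'   `c(mean, sd)` of the Gaussian FRET emission of a state.
#' @param k_assoc One-phase association rate constant, min^-1.
#' @param plateau,y0 Asymptotic and initial unwound fractions.
#' @param components A 3-row data frame with columns `mean`, `sd`, `weight`
#'   describing the donor-only, unwound and wound FRET peaks (in that order
#'   of increasing mean). Weights of the two signal components are rescaled
#'   at sampling time to match the instantaneous unwound fraction; the
#'   donor-only weight is the fraction of molecules in the artifact peak.
#' @param k_arrival,k_dissoc,k_clamp,clamp_exit Binding-archetype rates, s^-1.
#' @return A list with class `smfret_kinetics` (and a subclass naming the
#'   archetype).
#' @examples
#' binding_kinetics(k_arrival = 0.0125, k_dissoc = 0.204, k_clamp = 0)
#' @name kinetics_params
NULL

check_rate <- function(x, name, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
      x < 0 || (!allow_zero && x == 0)) {
    abort(sprintf("`%s` must be a single finite %s rate", name,
                  if (allow_zero) "non-negative" else "positive"),
          class = "smfret_invalid_parameter")
  }
  as.numeric(x)
}

check_emission <- function(x, name, sd_zero_ok = FALSE) {
  if (!is.numeric(x) || length(x) != 2 || any(!is.finite(x))) {
    abort(sprintf("`%s` must be c(mean, sd)", name),
          class = "smfret_invalid_parameter")
  }
  if (x[1] < 0 || x[1] > 1) {
    abort(sprintf("`%s` mean must lie in [0, 1]", name),
          class = "smfret_invalid_parameter")
  }
  if (x[2] < 0 || (!sd_zero_ok && x[2] == 0)) {
    abort(sprintf("`%s` sd must be positive", name),
          class = "smfret_invalid_parameter")
  }
  setNames(as.numeric(x), c("mean", "sd"))
}

#' @rdname kinetics_params
#' @export
two_state_kinetics <- function(k_unwind, k_rewind,
                               fret_wound = c(0.6, 0.05),
                               fret_unwound = c(0.3, 0.05)) {
  structure(
    list(k_unwind = check_rate(k_unwind, "k_unwind", allow_zero = TRUE),
         k_rewind = check_rate(k_rewind, "k_rewind", allow_zero = TRUE),
         fret_wound = check_emission(fret_wound, "fret_wound", sd_zero_ok = TRUE),
         fret_unwound = check_emission(fret_unwound, "fret_unwound", sd_zero_ok = TRUE)),
    class = c("two_state_kinetics", "smfret_kinetics")
  )
}

#' @rdname kinetics_params
#' @export
snapshot_kinetics <- function(k_assoc, plateau, y0,
                              components = snapshot_components()) {
  check_rate(k_assoc, "k_assoc", allow_zero = TRUE)
  components <- as_tibble(components)
  stopifnot(all(c("mean", "sd", "weight") %in% names(components)),
            nrow(components) == 3)
  if (any(components$weight < 0) || any(components$sd <= 0)) {
    abort("component weights must be >= 0 and sds > 0",
          class = "smfret_invalid_parameter")
  }
  if (!(y0 >= 0 && plateau <= 1 &&
        ((y0 <= plateau) || (plateau >= 0 && y0 <= 1)))) {
    abort("require 0 <= y0, plateau <= 1", class = "smfret_invalid_parameter")
  }
  structure(
    list(k_assoc = as.numeric(k_assoc), plateau = as.numeric(plateau),
         y0 = as.numeric(y0),
         components = arrange(components, .data$mean)),
    class = c("snapshot_kinetics", "smfret_kinetics")
  )
}

#' @rdname kinetics_params
#' @param target Which mismatch geometry the default peaks emulate:
#'   `"pam_distal"` (classification window near 0.18-0.51) or
#'   `"pam_proximal"` (window near 0.14-0.47).
#' @param donor_only_weight Fraction of molecules in the donor-only artifact
#'   peak.
#' @export
snapshot_components <- function(target = c("pam_distal", "pam_proximal"),
                                donor_only_weight = 0.10) {
  target <- match.arg(target)
  if (target == "pam_distal") {
    means <- c(0.05, 0.35, 0.65)
  } else {
    means <- c(0.04, 0.30, 0.62)
  }
  tibble(
    component = c("donor_only", "unwound", "wound"),
    mean = means,
    sd = c(0.045, 0.065, 0.065),
    weight = c(donor_only_weight, (1 - donor_only_weight) / 2,
               (1 - donor_only_weight) / 2)
  )
}

#' @rdname kinetics_params
#' @export
binding_kinetics <- function(k_arrival, k_dissoc, k_clamp = 0,
                             clamp_exit = 0.1,
                             fret_specific = c(0.85, 0.07),
                             fret_clamp = c(0.30, 0.07)) {
  fs <- check_emission(fret_specific, "fret_specific", sd_zero_ok = TRUE)
  fc <- check_emission(fret_clamp, "fret_clamp", sd_zero_ok = TRUE)
  if (fs[["mean"]] <= fc[["mean"]]) {
    abort("fret_specific mean must exceed fret_clamp mean",
          class = "smfret_invalid_parameter")
  }
  structure(
    list(k_arrival = check_rate(k_arrival, "k_arrival"),
         k_dissoc = check_rate(k_dissoc, "k_dissoc"),
         k_clamp = check_rate(k_clamp, "k_clamp"),
         clamp_exit = check_rate(clamp_exit, "clamp_exit"),
         fret_specific = fs, fret_clamp = fc),
    class = c("binding_kinetics", "smfret_kinetics")
  )
}

#' Detector noise and photophysics models
#'
#' `noise_model()` describes the rendered intensity signal: the constant
#' total (donor + acceptor) emission of an active molecule under donor
#' excitation, additive Gaussian read noise per channel, and a per-channel
#' background level. Poisson (shot-noise) rendering can be switched on with
#' `shot_noise = TRUE`, in which case each channel is drawn from a Poisson
#' law with the noiseless intensity as its mean; Gaussian noise is the
#' default.
#'
#' `photophysics_model()` collects dye-failure processes: single-step
#' photobleaching of each dye (exponential, in s^-1 of illuminated time) and
#' the fraction of molecules whose acceptor is dark from the start
#' (mislabeled or pre-bleached), which the acceptor-presence filter is
#' designed to remove.
#'
#' @param total_intensity Summed donor + acceptor signal of one molecule,
#'   arbitrary units.
#' @param intensity_sd Gaussian read-noise sd per channel, same units.
#' @param background Background level added to each channel.
#' @param shot_noise If `TRUE`, render channels as Poisson counts.
#' @param donor_bleach,acceptor_bleach Photobleaching rates, s^-1.
#' @param inactive_acceptor_fraction Probability a molecule's acceptor is
#'   inactive from frame 0.
#' @param labeled_fraction Probability a molecule carries the donor label at
#'   all (unlabeled molecules render as background).
#' @return A list of class `noise_model` / `photophysics_model`.
#' @export
noise_model <- function(total_intensity = 1000, intensity_sd = 30,
                        background = 50, shot_noise = FALSE) {
  if (total_intensity <= 0 || intensity_sd < 0 || background < 0) {
    abort("total_intensity must be > 0; intensity_sd and background >= 0",
          class = "smfret_invalid_parameter")
  }
  structure(list(total_intensity = total_intensity,
                 intensity_sd = intensity_sd,
                 background = background,
                 shot_noise = isTRUE(shot_noise)),
            class = "noise_model")
}

#' @rdname noise_model
#' @export
photophysics_model <- function(donor_bleach = 0, acceptor_bleach = 0,
                               inactive_acceptor_fraction = 0,
                               labeled_fraction = 1) {
  check_rate(donor_bleach, "donor_bleach")
  check_rate(acceptor_bleach, "acceptor_bleach")
  if (inactive_acceptor_fraction < 0 || inactive_acceptor_fraction > 1 ||
      labeled_fraction < 0 || labeled_fraction > 1) {
    abort("fractions must lie in [0, 1]", class = "smfret_invalid_parameter")
  }
  structure(list(donor_bleach = donor_bleach,
                 acceptor_bleach = acceptor_bleach,
                 inactive_acceptor_fraction = inactive_acceptor_fraction,
                 labeled_fraction = labeled_fraction),
            class = "photophysics_model")
}

#' Full simulation configuration
#'
#' Bundles the kinetic archetype, movie schedule, noise and photophysics
#' models with the sample size and master seed. An identical `sim_config()`
#' (including `seed`) reproduces a bit-identical dataset.
#'
#' @param kinetics A [two_state_kinetics()], [snapshot_kinetics()] or
#'   [binding_kinetics()] object.
#' @param schedule An [excitation_schedule()]; defaults to the archetype's
#'   standard movie layout.
#' @param n_molecules Number of molecules to simulate.
#' @param noise A [noise_model()].
#' @param photophysics A [photophysics_model()].
#' @param seed Master integer seed; per-molecule streams are derived from it.
#' @param condition Free-text condition label carried into outputs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(kinetics, schedule = NULL, n_molecules = 100,
                       noise = noise_model(),
                       photophysics = photophysics_model(),
                       seed = 1L, condition = "synthetic") {
  stopifnot(inherits(kinetics, "smfret_kinetics"),
            inherits(noise, "noise_model"),
            inherits(photophysics, "photophysics_model"))
  if (n_molecules < 1) {
    abort("n_molecules must be >= 1", class = "smfret_invalid_parameter")
  }
  if (is.null(schedule)) {
    schedule <- default_schedule(kinetics)
  }
  stopifnot(inherits(schedule, "fret_schedule"))
  structure(list(kinetics = kinetics, schedule = schedule,
                 n_molecules = as.integer(n_molecules), noise = noise,
                 photophysics = photophysics, seed = as.integer(seed),
                 condition = condition),
            class = "sim_config")
}

default_schedule <- function(kinetics) {
  if (inherits(kinetics, "binding_kinetics")) {
    if (kinetics$k_clamp > 0) schedule_muts_atp() else schedule_muts_adp()
  } else {
    schedule_cas9_snapshot()
  }
}

# Deterministic per-molecule sub-seeds derived from the master seed. The
# caller's RNG state is restored afterwards so simulation cannot perturb an
# enclosing analysis that also uses the RNG.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
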