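#' Simulate a continuous-time Markov state path
#'
#' Draws one realization of the generative kinetic scheme by the Gillespie
#' algorithm: sojourn times in each state are exponential with the state's
#' total exit rate, and the exit branches among target states in proportion
#' to their rates.
#'
#' For [two_state_kinetics()] the states are `"wound"` and `"unwound"`; for
#' [binding_kinetics()] they are `"dark"` (no protein in view), `"bound"`
#' (high-FRET specific binding) and `"clamp"` (low-FRET sliding clamp).
#'
#' @param kinetics A [two_state_kinetics()] or [binding_kinetics()] object.
#' @param duration Total simulated time, seconds.
#' @param start_state Initial state; defaults to `"wound"` for the two-state
#'   scheme (drawn from the stationary law when `stationary_start = TRUE`)
#'   and `"dark"` for the binding scheme.
#' @param stationary_start For the two-state scheme, draw the initial state
#'   from the stationary distribution instead of `start_state`.
#' @param seed Optional seed applied locally (caller's RNG state restored).
#' @return Tibble with columns `state`, `t_entry`, `t_exit`; the last row's
#'   `t_exit` equals `duration` (sojourn truncated by the end of observation).
#' @examples
#' k <- binding_kinetics(k_arrival = 0.05, k_dissoc = 0.2, k_clamp = 0.3)
#' simulate_ctmc_path(k, duration = 100, seed = 1)
#' @export
simulate_ctmc_path <- function(kinetics, duration, start_state = NULL,
                               stationary_start = FALSE, seed = NULL) {
  if (!is.numeric(duration) || length(duration) != 1 ||
      !is.finite(duration) || duration <= 0) {
    abort("`duration` must be a single positive number of seconds",
          class = "smfret_invalid_parameter")
  }
  trans <- ctmc_transitions(kinetics)
  if (!is.null(seed)) {
    return(with_seed(seed, simulate_ctmc_path(kinetics, duration,
                                              start_state, stationary_start)))
  }
  state <- start_state %||% default_start_state(kinetics, stationary_start)
  if (!state %in% names(trans)) {
    abort(sprintf("unknown start state '%s'", state),
          class = "smfret_invalid_parameter")
  }
  cap <- 64L
  states <- character(cap); t_entry <- numeric(cap); t_exit <- numeric(cap)
  n <- 0L
  t <- 0
  while (t < duration) {
    rates <- trans[[state]]
    total <- sum(rates)
    exit <- if (total <= 0) Inf else t + rexp(1, total)
    n <- n + 1L
    if (n > cap) { # amortized doubling
      cap <- cap * 2L
      length(states) <- cap; length(t_entry) <- cap; length(t_exit) <- cap
    }
    states[n] <- state; t_entry[n] <- t; t_exit[n] <- min(exit, duration)
    if (exit >= duration) break
    state <- if (length(rates) == 1) names(rates) else {
      sample(names(rates), 1L, prob = rates)
    }
    t <- exit
  }
  tibble(state = states[seq_len(n)], t_entry = t_entry[seq_len(n)],
         t_exit = t_exit[seq_len(n)])
}

ctmc_transitions <- function(kinetics) {
  if (inherits(kinetics, "two_state_kinetics")) {
    list(wound = c(unwound = kinetics$k_unwind),
         unwound = c(wound = kinetics$k_rewind))
  } else if (inherits(kinetics, "binding_kinetics")) {
    list(dark = c(bound = kinetics$k_arrival),
         bound = c(dark = kinetics$k_dissoc, clamp = kinetics$k_clamp),
         clamp = c(dark = kinetics$clamp_exit))
  } else {
    abort("no continuous-time scheme is defined for this kinetics object",
          class = "smfret_invalid_parameter")
  }
}

default_start_state <- function(kinetics, stationary_start) {
  if (inherits(kinetics, "binding_kinetics")) return("dark")
  if (stationary_start) {
    p_unwound <- kinetics$k_unwind / (kinetics$k_unwind + kinetics$k_rewind)
    if (runif(1) < p_unwound) "unwound" else "wound"
  } else {
    "wound"
  }
}

state_emissions <- function(kinetics) {
  if (inherits(kinetics, "two_state_kinetics")) {
    list(wound = kinetics$fret_wound, unwound = kinetics$fret_unwound,
         dark = NULL)
  } else if (inherits(kinetics, "binding_kinetics")) {
    list(bound = kinetics$fret_specific, clamp = kinetics$fret_clamp,
         dark = NULL)
  } else {
    abort("no per-state emissions for this kinetics object",
          class = "smfret_invalid_parameter")
  }
}

#' Ground-truth state per frame
#'
#' Samples a state path at each frame midpoint of a schedule — the same
#' instant [render_trace()] reads the path — giving the per-frame ground
#' truth against which idealization accuracy is measured.
#'
#' @param path Output of [simulate_ctmc_path()].
#' @param schedule An [excitation_schedule()].
#' @return Tibble `frame`, `time_s`, `excitation`, `state`.
#' @export
frame_states <- function(path, schedule, .frames = NULL) {
  fr <- .frames %||% schedule_frames(schedule)
  dt <- attr(schedule, "frame_interval")
  mid <- fr$time_s + dt / 2
  idx <- findInterval(mid, path$t_entry)
  idx[idx < 1L] <- 1L
  fr$state <- path$state[idx]
  fr
}

#' Render a fluorescence intensity trace from a state path
#'
#' Converts a continuous-time state path into per-frame donor/acceptor
#' intensities under the movie's excitation schedule. During donor-excitation
#' frames an active molecule in a FRET state with drawn efficiency `E` emits
#' `acceptor = background + E * total` and `donor = background + (1 - E) *
#' total` (plus read noise); dark states emit background only. Direct
#' acceptor-excitation frames report acceptor presence (full intensity when
#' the acceptor is active and unbleached). Photobleaching truncates the
#' corresponding dye's signal; an inactive acceptor renders as a donor-only
#' molecule throughout.
#'
#' @param path A state path from [simulate_ctmc_path()] whose duration covers
#'   the schedule.
#' @param config A [sim_config()].
#' @param molecule_id Identifier stored in the output.
#' @param seed Optional local seed.
#' @return Tibble with columns `molecule`, `frame`, `time_s`, `excitation`,
#'   `donor`, `acceptor`, with attributes `frame_interval` and `condition`.
#' @export
render_trace <- function(path, config, molecule_id = 1L, seed = NULL,
                         .frames = NULL) {
  if (!is.null(seed)) {
    return(with_seed(seed, render_trace(path, config, molecule_id,
                                        .frames = .frames)))
  }
  schedule <- config$schedule
  dt <- attr(schedule, "frame_interval")
  movie_t <- n_frames(schedule) * dt
  if (max(path$t_exit) < movie_t - 1e-9) {
    abort("state path is shorter than the excitation schedule",
          class = "smfret_contract_violation")
  }
  noise <- config$noise
  phys <- config$photophysics
  emis <- state_emissions(config$kinetics)

  fr <- frame_states(path, schedule, .frames = .frames)
  nf <- nrow(fr)
  mid <- fr$time_s + dt / 2

  labeled <- runif(1) < phys$labeled_fraction
  acceptor_active <- runif(1) >= phys$inactive_acceptor_fraction
  t_donor_bleach <- if (phys$donor_bleach > 0) rexp(1, phys$donor_bleach) else Inf
  t_acceptor_bleach <- if (phys$acceptor_bleach > 0) rexp(1, phys$acceptor_bleach) else Inf

  donor_mean <- rep(noise$background, nf)
  acceptor_mean <- rep(noise$background, nf)

  is_dx <- fr$excitation == "donor_ex"
  acceptor_ok <- acceptor_active & (mid < t_acceptor_bleach)

  # donor-excitation frames: split total emission by the state's drawn FRET
  emis_mean <- vapply(emis, function(e) if (is.null(e)) NA_real_ else e[["mean"]],
                      numeric(1))
  emis_sd <- vapply(emis, function(e) if (is.null(e)) NA_real_ else e[["sd"]],
                    numeric(1))
  state_mean <- unname(emis_mean[fr$state])
  state_sd <- unname(emis_sd[fr$state])
  bright <- is_dx & labeled & !is.na(state_mean) & (mid < t_donor_bleach)
  if (any(bright)) {
    e <- rnorm(sum(bright), state_mean[bright], state_sd[bright])
    e_eff <- ifelse(acceptor_ok[bright], e, 0) # dark acceptor: all photons to donor
    acceptor_mean[bright] <- acceptor_mean[bright] + e_eff * noise$total_intensity
    donor_mean[bright] <- donor_mean[bright] + (1 - e_eff) * noise$total_intensity
  }

  # direct acceptor excitation reports acceptor presence
  is_ax <- !is_dx
  acceptor_mean[is_ax & acceptor_ok] <-
    acceptor_mean[is_ax & acceptor_ok] + noise$total_intensity

  if (noise$shot_noise) {
    donor <- stats::rpois(nf, pmax(donor_mean, 0))
    acceptor <- stats::rpois(nf, pmax(acceptor_mean, 0))
  } else {
    donor <- donor_mean + rnorm(nf, 0, noise$intensity_sd)
    acceptor <- acceptor_mean + rnorm(nf, 0, noise$intensity_sd)
  }

  out <- tibble(molecule = molecule_id, frame = fr$frame, time_s = fr$time_s,
                excitation = fr$excitation, donor = donor, acceptor = acceptor)
  attr(out, "frame_interval") <- dt
  attr(out, "condition") <- config$condition
  out
}

#' Simulate a snapshot (equilibrium or time-course) FRET experiment
#'
#' Emulates the short-movie snapshot design: fields of view are imaged at a
#' series of timepoints after adding the unwinding enzyme, and each molecule
#' contributes five FRET histogram values per timepoint. The unwound
#' probability at time `t` (minutes) follows the one-phase association law
#' `y0 + (plateau - y0) * (1 - exp(-k t))`; molecules are drawn
#' quasi-statically at the sampling instant. A molecule falls in the
#' donor-only artifact peak with the artifact component's weight; otherwise
#' it is unwound with the time-dependent probability, and its five values are
#' drawn from the matching Gaussian component.
#'
#' @param config A [sim_config()] whose kinetics is [snapshot_kinetics()].
#' @param timepoints Sampling times in minutes, sorted non-negative. A single
#'   large value emulates an equilibrium measurement.
#' @param values_per_molecule Histogram values drawn per molecule (the frames
#'   3-7 selection yields five).
#' @return Tibble of class `snapshot_dataset`: `t_min`, `molecule`,
#'   `component` (generative truth), `value_rank`, `fret`.
#' @examples
#' cfg <- sim_config(snapshot_kinetics(k_assoc = 0.3, plateau = 0.79, y0 = 0.35),
#'                   n_molecules = 200, seed = 7)
#' snap <- simulate_snapshot_experiment(cfg, timepoints = c(1, 2, 4, 10))
#' @export
simulate_snapshot_experiment <- function(config, timepoints,
                                         values_per_molecule = 5L) {
  stopifnot(inherits(config, "sim_config"))
  kin <- config$kinetics
  if (!inherits(kin, "snapshot_kinetics")) {
    abort("snapshot simulation requires snapshot_kinetics",
          class = "smfret_invalid_parameter")
  }
  if (length(timepoints) == 0) {
    abort("`timepoints` must be a non-empty numeric vector (minutes)",
          class = "smfret_invalid_parameter")
  }
  if (any(timepoints < 0) || is.unsorted(timepoints)) {
    abort("`timepoints` must be sorted and non-negative",
          class = "smfret_invalid_parameter")
  }
  comp <- kin$components
  seeds <- derive_seeds(config$seed, length(timepoints))
  n <- config$n_molecules
  m <- values_per_molecule

  out <- purrr::map2(timepoints, seeds, function(t, s) {
    with_seed(s, {
      p_unwound <- one_phase_association(t, kin$y0, kin$plateau, kin$k_assoc)
      artifact <- runif(n) < comp$weight[1]
      unwound <- runif(n) < p_unwound
      comp_idx <- ifelse(artifact, 1L, ifelse(unwound, 2L, 3L))
      idx <- rep(comp_idx, each = m)
      tibble(
        t_min = t,
        molecule = rep(seq_len(n), each = m),
        component = comp$component[idx],
        value_rank = rep(seq_len(m), n),
        fret = rnorm(n * m, comp$mean[idx], comp$sd[idx])
      )
    })
  })
  out <- bind_rows(out)
  attr(out, "config") <- config
  class(out) <- c("snapshot_dataset", class(out))
  out
}

#' One-phase association model function
#'
#' `y = y0 + (plateau - y0) * (1 - exp(-k * t))`.
#'
#' @param t Time (minutes in the snapshot design).
#' @param y0 Value at `t = 0`.
#' @param plateau Asymptote as `t -> Inf`.
#' @param k Association rate constant (inverse time units of `t`).
#' @export
one_phase_association <- function(t, y0, plateau, k) {
  y0 + (plateau - y0) * (1 - exp(-k * t))
}

#' Simulate a continuous binding or two-state movie experiment
#'
#' `simulate_binding_experiment()` renders full-length movies of repeated
#' protein binding at a mismatch (the sliding-clamp archetype when
#' `k_clamp > 0`, the dissociation-only archetype when `k_clamp = 0`).
#' `simulate_twostate_experiment()` renders movies of a DNA molecule
#' interconverting between wound and unwound FRET states. Both derive one
#' RNG stream per molecule from the master seed, so a dataset is bit-identical
#' for an identical [sim_config()].
#'
#' @param config A [sim_config()] with [binding_kinetics()] (or
#'   [two_state_kinetics()] for the two-state variant).
#' @param stationary_start Two-state variant only: draw each molecule's
#'   initial state from the stationary law.
#' @return A list of class `trace_set`: `traces` (per-frame tibble over all
#'   molecules), `paths` (ground-truth state paths, with `molecule`), and the
#'   `config`.
#' @export
simulate_binding_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!inherits(config$kinetics, "binding_kinetics")) {
    abort("binding simulation requires binding_kinetics",
          class = "smfret_invalid_parameter")
  }
  simulate_movie_set(config)
}

#' @rdname simulate_binding_experiment
#' @export
simulate_twostate_experiment <- function(config, stationary_start = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (!inherits(config$kinetics, "two_state_kinetics")) {
    abort("two-state simulation requires two_state_kinetics",
          class = "smfret_invalid_parameter")
  }
  simulate_movie_set(config, stationary_start = stationary_start)
}

simulate_movie_set <- function(config, stationary_start = FALSE) {
  dt <- attr(config$schedule, "frame_interval")
  movie_t <- n_frames(config$schedule) * dt
  seeds <- derive_seeds(config$seed, config$n_molecules)
  sched_frames <- schedule_frames(config$schedule)
  sims <- purrr::map(seq_len(config$n_molecules), function(i) {
    with_seed(seeds[i], {
      path <- simulate_ctmc_path(config$kinetics, duration = movie_t,
                                 stationary_start = stationary_start)
      trace <- render_trace(path, config, molecule_id = i,
                            .frames = sched_frames)
      list(trace = trace, path = mutate(path, molecule = i, .before = 1))
    })
  })
  traces <- bind_rows(purrr::map(sims, "trace"))
  attr(traces, "frame_interval") <- dt
  attr(traces, "condition") <- config$condition
  structure(list(traces = traces,
                 paths = bind_rows(purrr::map(sims, "path")),
                 config = config),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %d molecules x %d frames (%.0f ms frames), condition '%s'\n",
              x$config$n_molecules, n_frames(x$config$schedule),
              1000 * attr(x$config$schedule, "frame_interval"),
              x$config$condition))
  invisible(x)
}
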