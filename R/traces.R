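#' FRET efficiency from a two-color intensity trace
#'
#' Computes the proximity-ratio FRET efficiency for every donor-excitation
#' frame of a trace: `E = (IA - bA) / ((IA - bA) + gamma * (ID - bD))`, where
#' `IA`/`ID` are the raw acceptor/donor intensities, `bA`/`bD` the channel
#' backgrounds, and `gamma` the detection-correction factor (1 for an
#' uncorrected proximity ratio). Frames whose corrected total intensity is
#' not positive (e.g. after photobleaching) yield `NA` rather than an error.
#'
#' @param traces A trace tibble (one or more molecules) with columns
#'   `molecule`, `frame`, `time_s`, `excitation`, `donor`, `acceptor`, as
#'   produced by [render_trace()] or read by [read_traces_csv()].
#' @param background_donor,background_acceptor Per-channel background levels
#'   subtracted before forming the ratio (arbitrary units).
#' @param gamma Detection correction factor, must be positive.
#' @return A tibble with columns `molecule`, `frame`, `time_s`, `fret`
#'   containing only donor-excitation frames; attribute `frame_interval` is
#'   carried over.
#' @examples
#' cfg <- sim_config(two_state_kinetics(0.5, 0.5), n_molecules = 2, seed = 1)
#' ts <- simulate_twostate_experiment(cfg)
#' compute_fret(ts$traces, background_donor = 50, background_acceptor = 50)
#' @export
compute_fret <- function(traces, background_donor = 0, background_acceptor = 0,
                         gamma = 1) {
  if (!is.numeric(gamma) || length(gamma) != 1 || !is.finite(gamma) ||
      gamma <= 0) {
    abort("`gamma` must be a single positive number",
          class = "smfret_invalid_parameter")
  }
  if (!all(is.finite(c(background_donor, background_acceptor)))) {
    abort("backgrounds must be finite", class = "smfret_invalid_parameter")
  }
  out <- traces |>
    filter(.data$excitation == "donor_ex") |>
    mutate(
      a = .data$acceptor - background_acceptor,
      d = .data$donor - background_donor,
      denom = .data$a + gamma * .data$d,
      fret = ifelse(.data$denom > 0, .data$a / .data$denom, NA_real_)
    ) |>
    select("molecule", "frame", "time_s", "fret")
  attr(out, "frame_interval") <- attr(traces, "frame_interval")
  out
}

#' Acceptor-presence filter
#'
#' Uses the direct acceptor-excitation frames at the end of a movie to decide
#' whether each molecule carries an active acceptor dye: a molecule passes
#' when its median acceptor intensity over the final acceptor-excitation
#' segment exceeds `background + threshold`. Molecules with a missing or
#' photobleached acceptor produce donor-only FRET artifacts and are removed
#' from histogram analysis by this filter.
#'
#' @param traces A trace tibble (see [compute_fret()]).
#' @param threshold Required margin above background, arbitrary units.
#' @param background Acceptor-channel background level.
#' @return Tibble `molecule`, `acceptor_present` (logical).
#' @export
acceptor_present <- function(traces, threshold, background = 0) {
  ax <- filter(traces, .data$excitation == "acceptor_ex")
  if (nrow(ax) == 0) {
    abort("schedule has no acceptor-excitation frames; cannot apply the acceptor filter",
          class = "smfret_contract_violation")
  }
  # final acceptor-excitation segment = acceptor frames after the last
  # donor-excitation frame (or all of them if the movie has none)
  last_dx <- traces |>
    filter(.data$excitation == "donor_ex") |>
    group_by(.data$molecule) |>
    summarise(last_dx = max(.data$frame), .groups = "drop")
  ax |>
    left_join(last_dx, by = "molecule") |>
    mutate(last_dx = ifelse(is.na(.data$last_dx), -1L, .data$last_dx)) |>
    group_by(.data$molecule) |>
    summarise(
      acceptor_present = median(.data$acceptor[.data$frame > .data$last_dx]) >
        background + threshold,
      .groups = "drop"
    )
}

#' Keep only molecules that pass the acceptor filter
#'
#' Convenience wrapper around [acceptor_present()]; the input is never
#' mutated and the result is a subset of its rows.
#'
#' @inheritParams acceptor_present
#' @return The filtered trace tibble.
#' @export
filter_acceptor_present <- function(traces, threshold, background = 0) {
  keep <- acceptor_present(traces, threshold, background)
  out <- dplyr::semi_join(traces,
                          filter(keep, .data$acceptor_present),
                          by = "molecule")
  attr(out, "frame_interval") <- attr(traces, "frame_interval")
  attr(out, "condition") <- attr(traces, "condition")
  out
}

#' Histogram-frame selection
#'
#' Selects each molecule's FRET values at donor-excitation frames 3 to 7
#' (1-based ordinals over that molecule's donor-excitation frames) — the five
#' values per molecule that enter population FRET histograms. Frames with a
#' missing FRET value are dropped from the selection.
#'
#' @param fret A FRET tibble from [compute_fret()] (columns `molecule`,
#'   `frame`, `fret`).
#' @return Tibble `molecule`, `frame`, `fret` restricted to the selected
#'   frames.
#' @export
select_histogram_frames <- function(fret) {
  counts <- fret |>
    group_by(.data$molecule) |>
    summarise(n = dplyr::n(), .groups = "drop")
  if (any(counts$n < 7)) {
    abort("every molecule needs at least 7 donor-excitation frames",
          class = "smfret_contract_violation")
  }
  fret |>
    group_by(.data$molecule) |>
    mutate(ordinal = row_number()) |>
    ungroup() |>
    filter(.data$ordinal >= 3, .data$ordinal <= 7, !is.na(.data$fret)) |>
    select("molecule", "frame", "fret")
}
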