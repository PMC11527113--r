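#' Read and write traces as long-format CSV
#'
#' Trace datasets are stored as a flat, diff-able CSV with one row per frame:
#' `molecule, frame, time_s, excitation, donor, acceptor, frame_interval`
#' (the last column is constant and carries the frame time so a file is
#' self-describing). UTF-8, '.' decimal separator, header row.
#'
#' @param traces A trace tibble.
#' @param path File path.
#' @return `read_traces_csv()` returns the trace tibble with its
#'   `frame_interval` attribute restored.
#' @export
write_traces_csv <- function(traces, path) {
  out <- mutate(traces, frame_interval = attr(traces, "frame_interval"))
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  needed <- c("molecule", "frame", "excitation", "donor", "acceptor")
  if (!all(needed %in% names(df))) {
    abort(sprintf("trace CSV must have columns %s",
                  paste(needed, collapse = ", ")),
          class = "smfret_validation_error")
  }
  dt <- unique(df$frame_interval)
  if (length(dt) != 1 || !is.finite(dt)) {
    abort("trace CSV must carry a single frame_interval value",
          class = "smfret_validation_error")
  }
  if (!"time_s" %in% names(df)) df$time_s <- df$frame * dt
  out <- select(df, "molecule", "frame", "time_s", "excitation",
                "donor", "acceptor")
  attr(out, "frame_interval") <- dt
  out
}

#' Read a run configuration
#'
#' Run configurations are YAML (or JSON) files with a `mode`, a `seed`, an
#' optional `simulate` block (kinetic archetype and parameters), an optional
#' `analysis` block (thresholds, backgrounds, HMM settings) and input/output
#' paths. See [run_pipeline()] for the recognised modes.
#'
#' @param path Path to a YAML or JSON config file.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file '%s' not found", path),
          class = "smfret_validation_error")
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A config list.
#' @export
validate_run_config <- function(cfg) {
  modes <- c("simulate", "analyze-cas9-timecourse", "analyze-cas9-equilibrium",
             "analyze-muts-adp", "analyze-muts-atp", "recover")
  if (is.null(cfg$mode) || !cfg$mode %in% modes) {
    abort(sprintf("config `mode` must be one of: %s",
                  paste(modes, collapse = ", ")),
          class = "smfret_validation_error")
  }
  needs_sim <- cfg$mode %in% c("simulate", "recover")
  if (needs_sim && is.null(cfg$simulate)) {
    abort(sprintf("mode '%s' requires a `simulate` block", cfg$mode),
          class = "smfret_validation_error")
  }
  needs_input <- startsWith(cfg$mode, "analyze")
  if (needs_input && is.null(cfg$input)) {
    abort(sprintf("mode '%s' requires an `input` path", cfg$mode),
          class = "smfret_validation_error")
  }
  cfg$seed <- cfg$seed %||% 1L
  structure(cfg, class = c("run_config", "list"))
}

#' Build a [sim_config()] from a config list
#'
#' @param lst The `simulate` block of a run config: `archetype`
#'   (`"two_state"`, `"snapshot"`, `"binding"`), a `kinetics` list of rate
#'   parameters, and optional `n_molecules`, `schedule`
#'   (`"cas9_snapshot"`, `"muts_adp"`, `"muts_atp"`), `noise`,
#'   `photophysics`, `condition` entries.
#' @param seed Master seed.
#' @return A [sim_config()].
#' @export
sim_config_from_list <- function(lst, seed = 1L) {
  kin_args <- lst$kinetics %||% list()
  kin <- switch(lst$archetype %||% "",
    two_state = do.call(two_state_kinetics, kin_args),
    snapshot = do.call(snapshot_kinetics, kin_args),
    binding = do.call(binding_kinetics, kin_args),
    abort("simulate block needs archetype: two_state, snapshot or binding",
          class = "smfret_validation_error")
  )
  schedule <- if (!is.null(lst$schedule)) {
    switch(lst$schedule,
           cas9_snapshot = schedule_cas9_snapshot(),
           muts_adp = schedule_muts_adp(),
           muts_atp = schedule_muts_atp(),
           abort("unknown schedule name", class = "smfret_validation_error"))
  } else NULL
  sim_config(
    kinetics = kin, schedule = schedule,
    n_molecules = lst$n_molecules %||% 100,
    noise = do.call(noise_model, lst$noise %||% list()),
    photophysics = do.call(photophysics_model, lst$photophysics %||% list()),
    seed = seed, condition = lst$condition %||% "synthetic"
  )
}

#' Run a configured simulation/analysis pipeline
#'
#' Executes one of the package's end-to-end pipelines and writes structured
#' outputs under `out_dir`: per-record CSV tables, a `summary.json` with all
#' fitted parameters and their standard errors, and a `provenance.json`
#' (config echo, package version, seed) from which the run can be
#' reproduced.
#'
#' Modes:
#' * `simulate` — generate a synthetic dataset (traces CSV + molecule index
#'   CSV for movie archetypes; snapshot values CSV for the snapshot
#'   archetype).
#' * `analyze-cas9-equilibrium` — three-Gaussian fit + intersection
#'   thresholds + unwound fraction on a snapshot values CSV.
#' * `analyze-cas9-timecourse` — per-timepoint unwound fractions and the
#'   one-phase association fit.
#' * `analyze-muts-adp` — event segmentation, t_on/t_off survival fits,
#'   `k_off` and `k'_on`.
#' * `analyze-muts-atp` — event segmentation, composite exit-rate fit,
#'   branch counting and rate decomposition, plus the arrival rate `k1`.
#' * `recover` — simulate then analyze, reporting generative vs recovered
#'   parameters side by side.
#'
#' @param config A `run_config` list (from [read_run_config()] /
#'   [validate_run_config()]) or a path to a config file.
#' @param out_dir Output directory (created if missing); overrides
#'   `config$out_dir`.
#' @param seed Overrides `config$seed`.
#' @return The summary list, invisibly; side effect: files under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  seed <- seed %||% config$seed
  out_dir <- out_dir %||% config$out_dir %||% "smfret-run"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  summary <- switch(
    config$mode,
    "simulate" = mode_simulate(config, out_dir, seed),
    "analyze-cas9-equilibrium" = mode_cas9_equilibrium(config, out_dir),
    "analyze-cas9-timecourse" = mode_cas9_timecourse(config, out_dir),
    "analyze-muts-adp" = mode_muts_adp(config, out_dir),
    "analyze-muts-atp" = mode_muts_atp(config, out_dir),
    "recover" = mode_recover(config, out_dir, seed)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  provenance <- list(
    package = "smfret",
    version = as.character(utils::packageVersion("smfret")),
    mode = config$mode, seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config)
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

analysis_opts <- function(config) {
  a <- config$analysis %||% list()
  list(
    background = a$background %||% 0,
    gamma = a$gamma %||% 1,
    bin_width = a$bin_width %||% 0.02,
    rule = if (!is.null(a$rule_lower) && !is.null(a$rule_upper)) {
      classification_rule(a$rule_lower, a$rule_upper)
    } else NULL,
    intensity_threshold = a$intensity_threshold %||% 300,
    fret_split = a$fret_split,
    min_clamp_frames = a$min_clamp_frames %||% 3L
  )
}

mode_simulate <- function(config, out_dir, seed) {
  sc <- sim_config_from_list(config$simulate, seed = seed)
  if (inherits(sc$kinetics, "snapshot_kinetics")) {
    tp <- config$simulate$timepoints %||% c(1, 2, 3, 4, 7, 10, 13, 20, 30, 45, 60)
    snap <- simulate_snapshot_experiment(sc, timepoints = tp)
    write.csv(snap, file.path(out_dir, "snapshot_values.csv"),
              row.names = FALSE, quote = FALSE)
    list(mode = "simulate", archetype = "snapshot",
         n_molecules = sc$n_molecules, n_timepoints = length(tp),
         n_values = nrow(snap))
  } else {
    ts <- if (inherits(sc$kinetics, "binding_kinetics")) {
      simulate_binding_experiment(sc)
    } else {
      simulate_twostate_experiment(sc)
    }
    write_traces_csv(ts$traces, file.path(out_dir, "traces.csv"))
    index <- ts$paths |>
      group_by(.data$molecule) |>
      summarise(n_sojourns = dplyr::n(),
                states = paste(unique(.data$state), collapse = "|"),
                .groups = "drop") |>
      mutate(condition = sc$condition)
    write.csv(index, file.path(out_dir, "molecule_index.csv"),
              row.names = FALSE, quote = FALSE)
    list(mode = "simulate",
         archetype = class(sc$kinetics)[1],
         n_molecules = sc$n_molecules,
         n_frames = n_frames(sc$schedule))
  }
}

read_snapshot_values <- function(path) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (!"fret" %in% names(df)) {
    abort("snapshot CSV needs a `fret` column", class = "smfret_validation_error")
  }
  if (nrow(df) == 0) {
    abort("snapshot CSV is empty", class = "smfret_insufficient_data")
  }
  df
}

mode_cas9_equilibrium <- function(config, out_dir) {
  opts <- analysis_opts(config)
  df <- read_snapshot_values(config$input)
  fit <- fit_three_gaussians(df$fret, bin_width = opts$bin_width)
  rule <- opts$rule %||% thresholds_rule(fit)
  fu <- fraction_unwound(df$fret, rule)
  write.csv(tidy(fit), file.path(out_dir, "mixture_components.csv"),
            row.names = FALSE, quote = FALSE)
  list(mode = config$mode,
       mixture = as.list(glance(fit)),
       rule = list(lower = rule$lower, upper = rule$upper,
                   source = if (is.null(opts$rule)) "intersection" else "fixed"),
       f_unwound = fu$f_unwound, counts = as.list(select(fu, -"f_unwound")))
}

mode_cas9_timecourse <- function(config, out_dir) {
  opts <- analysis_opts(config)
  df <- read_snapshot_values(config$input)
  if (!"t_min" %in% names(df)) {
    abort("timecourse CSV needs a `t_min` column", class = "smfret_validation_error")
  }
  tc <- fraction_unwound_timecourse(df, rule = opts$rule,
                                    bin_width = opts$bin_width)
  fit <- fit_one_phase_association(tc)
  write.csv(tc, file.path(out_dir, "timecourse.csv"),
            row.names = FALSE, quote = FALSE)
  list(mode = config$mode,
       association = c(as.list(setNames(fit$estimate, names(fit$estimate))),
                       list(se = as.list(fit$se),
                            k_per_s = unname(fit$estimate[["k"]]) / 60,
                            direction = fit$direction,
                            converged = fit$converged)))
}

load_events <- function(config, opts) {
  traces <- read_traces_csv(config$input)
  if (nrow(traces) == 0) {
    abort("trace CSV is empty", class = "smfret_insufficient_data")
  }
  segment_binding_events(
    traces,
    intensity_threshold = opts$intensity_threshold,
    fret_split = opts$fret_split,
    background = opts$background, gamma = opts$gamma,
    min_clamp_frames = opts$min_clamp_frames
  )
}

observation_stats <- function(config) {
  traces <- read_traces_csv(config$input)
  dx <- filter(traces, .data$excitation == "donor_ex")
  list(n_molecules = length(unique(traces$molecule)),
       observation_time = length(unique(dx$frame)) *
         attr(traces, "frame_interval"))
}

mode_muts_adp <- function(config, out_dir) {
  opts <- analysis_opts(config)
  events <- load_events(config, opts)
  write.csv(events, file.path(out_dir, "events.csv"),
            row.names = FALSE, quote = FALSE)
  ton <- events$t_sb[!events$censored]
  toff <- events$preceding_wait[!events$wait_censored &
                                  events$preceding_wait > 0]
  kin <- estimate_adp_kinetics(ton, toff)
  obs <- observation_stats(config)
  list(mode = config$mode, kinetics = as.list(kin),
       k1 = estimate_k1(events, obs$n_molecules, obs$observation_time),
       n_events = nrow(events))
}

mode_muts_atp <- function(config, out_dir) {
  opts <- analysis_opts(config)
  events <- load_events(config, opts)
  write.csv(events, file.path(out_dir, "events.csv"),
            row.names = FALSE, quote = FALSE)
  obs <- observation_stats(config)
  rates <- summarize_rate_set(events, obs$n_molecules, obs$observation_time,
                              condition = config$condition %||% NA_character_)
  list(mode = config$mode, rates = as.list(rates))
}

mode_recover <- function(config, out_dir, seed) {
  sim_dir <- file.path(out_dir, "simulated")
  sim_cfg <- config
  sim_cfg$mode <- "simulate"
  sim_summary <- run_pipeline(sim_cfg, out_dir = sim_dir, seed = seed)

  ana_cfg <- config
  ana_cfg$mode <- config$analyze_mode %||%
    abort("recover mode requires `analyze_mode`", class = "smfret_validation_error")
  ana_cfg$input <- file.path(sim_dir,
                             if (identical(config$simulate$archetype, "snapshot")) {
                               "snapshot_values.csv"
                             } else "traces.csv")
  ana_summary <- run_pipeline(ana_cfg, out_dir = file.path(out_dir, "analyzed"),
                              seed = seed)
  list(mode = "recover", seed = seed,
       generative = config$simulate$kinetics,
       simulated = sim_summary,
       recovered = ana_summary)
}
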