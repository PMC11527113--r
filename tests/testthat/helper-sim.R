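# shared fixture builders (everything is generated in code)

donor_only_schedule <- function(n_frames, frame_interval = 0.05) {
  excitation_schedule(
    data.frame(start_frame = 0L, end_frame = as.integer(n_frames),
               channel = "donor_ex"),
    frame_interval = frame_interval
  )
}

# minimal trace tibble built by hand (single molecule unless told otherwise)
make_trace <- function(donor, acceptor, excitation = NULL,
                       frame_interval = 0.05, molecule = 1L) {
  n <- length(donor)
  excitation <- excitation %||% rep("donor_ex", n)
  out <- tibble::tibble(
    molecule = molecule, frame = seq_len(n) - 1L,
    time_s = (seq_len(n) - 1L) * frame_interval,
    excitation = excitation, donor = donor, acceptor = acceptor
  )
  attr(out, "frame_interval") <- frame_interval
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# noiseless simulation settings: exact state means, no read noise
noiseless <- function() noise_model(total_intensity = 1000, intensity_sd = 0,
                                    background = 0)

# extended-acquisition binding schedule used for slow-rate recovery studies
long_adp_schedule <- function(n_donor = 3920L, frame_interval = 0.2) {
  excitation_schedule(
    data.frame(start_frame = c(0L, 10L, 10L + n_donor),
               end_frame = c(10L, 10L + n_donor, 20L + n_donor),
               channel = c("acceptor_ex", "donor_ex", "acceptor_ex")),
    frame_interval = frame_interval
  )
}

# one dissociation-rate recovery experiment: simulate ADP-archetype movies,
# segment events, survival fit of the uncensored specific-binding dwells
recover_koff <- function(k_dissoc, seed, n_molecules = 300,
                         schedule = long_adp_schedule()) {
  kin <- binding_kinetics(k_arrival = 0.0125, k_dissoc = k_dissoc, k_clamp = 0)
  cfg <- sim_config(kin, schedule = schedule, n_molecules = n_molecules,
                    seed = seed)
  ts <- simulate_binding_experiment(cfg)
  ev <- segment_binding_events(ts$traces, intensity_threshold = 300,
                               fret_split = 0.55, background = 50)
  ton <- ev$t_sb[!ev$censored]
  list(k = fit_single_exponential(one_minus_cdf(ton))$estimate[["k"]],
       n_uncensored = length(ton))
}
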