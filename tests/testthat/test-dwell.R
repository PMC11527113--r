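test_that("separable states are idealized exactly", {
  e <- rep(c(0.2, 0.7), each = 5, times = 10)
  traj <- tibble::tibble(frame = seq_along(e) - 1L,
                         time_s = (seq_along(e) - 1L) * 0.05, fret = e)
  fit <- hmm_idealize(traj)
  expect_equal(fit$path$state, as.integer(e > 0.45))
  expect_equal(fit$means, c(0.2, 0.7), tolerance = 1e-6)
  expect_false(fit$degenerate)
})

test_that("constant trajectories raise the degeneracy flag", {
  traj <- tibble::tibble(frame = 0:19, time_s = (0:19) * 0.05, fret = 0.5)
  fit <- hmm_idealize(traj)
  expect_true(fit$degenerate)
  expect_error(hmm_idealize(traj[1:5, ]), class = "smfret_contract_violation")
  expect_error(hmm_idealize(traj, n_states = 4),
               class = "smfret_invalid_parameter")
})

test_that("HMM and threshold idealization agree with ground truth on synthetic traces", {
  kin <- two_state_kinetics(0.5, 0.5, fret_wound = c(0.6, 0.05),
                            fret_unwound = c(0.3, 0.05))
  sched <- donor_only_schedule(400, 0.05)
  cfg <- sim_config(kin, schedule = sched, n_molecules = 100,
                    noise = noiseless(), seed = 61)
  ts <- simulate_twostate_experiment(cfg)
  fr <- compute_fret(ts$traces)
  mis_truth <- 0; mis_thresh <- 0; n_frames_total <- 0
  for (m in unique(fr$molecule)) {
    traj <- fr[fr$molecule == m, ]
    fit <- hmm_idealize(traj)
    truth <- frame_states(ts$paths[ts$paths$molecule == m, ], sched)
    truth_state <- as.integer(truth$state == "wound") # wound = high mean 0.6
    thr <- threshold_idealize(traj, split = 0.45)
    mis_truth <- mis_truth + sum(fit$path$state != truth_state)
    mis_thresh <- mis_thresh + sum(fit$path$state != thr$state)
    n_frames_total <- n_frames_total + nrow(traj)
  }
  expect_lt(mis_truth / n_frames_total, 0.02)
  expect_lt(mis_thresh / n_frames_total, 0.02)
})

test_that("dwell extraction counts runs with boundary censoring", {
  path <- tibble::tibble(state = c(0, 0, 1, 1, 1, 0))
  d <- extract_dwells(path, frame_interval = 0.05)
  expect_equal(d$duration_s, c(0.10, 0.15, 0.05))
  expect_equal(d$censored_left, c(TRUE, FALSE, FALSE))
  expect_equal(d$censored_right, c(FALSE, FALSE, TRUE))
  expect_equal(d$next_state, c(1, 0, NA))
  # single-state path: one fully censored dwell
  d2 <- extract_dwells(tibble::tibble(state = rep(1, 8)), 0.05)
  expect_equal(nrow(d2), 1)
  expect_true(d2$censored_left && d2$censored_right)
  # durations always sum to the trace's observation span
  expect_equal(sum(d$duration_s), 6 * 0.05)
})

test_that("uncensored dwell means match the generative rate", {
  kin <- two_state_kinetics(0.5, 0.5)
  sched <- donor_only_schedule(800, 0.05) # 40 s traces, mean dwell 2 s
  dwells <- purrr::map(1:160, function(i) {
    path <- simulate_ctmc_path(kin, duration = 40, seed = 1000 + i)
    fs <- frame_states(path, sched)
    extract_dwells(tibble::tibble(state = fs$state), 0.05)
  }) |> dplyr::bind_rows()
  ok <- dwells[!dwells$censored_left & !dwells$censored_right &
                 dwells$state == "wound", ]
  expect_gt(nrow(ok), 1000)
  expect_equal(mean(ok$duration_s), 2.0, tolerance = 0.05)
})

test_that("censored-dwell exclusion bias is directional when dwells approach trace length", {
  # mean dwell 20 s vs 40 s traces: completed dwells are biased short,
  # so the rate estimate can only overshoot
  kin <- two_state_kinetics(0.05, 0.05)
  sched <- donor_only_schedule(800, 0.05)
  dwells <- purrr::map(1:150, function(i) {
    path <- simulate_ctmc_path(kin, duration = 40, seed = 5000 + i)
    fs <- frame_states(path, sched)
    extract_dwells(tibble::tibble(state = fs$state), 0.05)
  }) |> dplyr::bind_rows()
  ok <- dwells[!dwells$censored_left & !dwells$censored_right, ]
  expect_gt(fit_exponential_mle(ok$duration_s), 0.05)
})

test_that("binding events are segmented with dwell, wait and outcome", {
  # hand-built noiseless movie: darkness, then one event at frames 100-150
  # switching high -> low at frame 130 (50 ms frames)
  n <- 300
  donor <- rep(0, n); acceptor <- rep(0, n)
  high <- 100:129; low <- 130:150
  donor[high + 1] <- 150; acceptor[high + 1] <- 850  # E = 0.85
  donor[low + 1] <- 700; acceptor[low + 1] <- 300    # E = 0.30
  tr <- make_trace(donor, acceptor, frame_interval = 0.05)
  ev <- segment_binding_events(tr, intensity_threshold = 300, fret_split = 0.55)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$t_sb, 30 * 0.05) # 1.5 s
  expect_equal(ev$outcome, "clamp")
  expect_false(ev$censored)
  expect_equal(ev$t_start, 100 * 0.05)
  expect_equal(ev$preceding_wait, 100 * 0.05)
  expect_error(segment_binding_events(tr, intensity_threshold = 0),
               class = "smfret_configuration_error")
})

test_that("ADP-archetype movies contain no clamp outcomes", {
  kin <- binding_kinetics(k_arrival = 0.02, k_dissoc = 0.2, k_clamp = 0)
  cfg <- sim_config(kin, n_molecules = 40, seed = 81)
  ts <- simulate_binding_experiment(cfg)
  ev <- segment_binding_events(ts$traces, intensity_threshold = 300,
                               fret_split = 0.55, background = 50)
  expect_gt(nrow(ev), 50)
  expect_false(any(ev$outcome == "clamp", na.rm = TRUE))
  expect_equal(count_branches(ev)$n_clamp, 0L)
})

test_that("ATP-archetype branch fractions match the rate ratio", {
  kin <- binding_kinetics(k_arrival = 0.0125, k_dissoc = 0.2, k_clamp = 0.3,
                          clamp_exit = 0.1)
  cfg <- sim_config(kin, n_molecules = 700, seed = 82, condition = "ATP")
  ts <- simulate_binding_experiment(cfg)
  ev <- segment_binding_events(ts$traces, intensity_threshold = 300,
                               background = 50)
  br <- count_branches(ev)
  n <- br$n_clamp + br$n_dissoc
  expect_gt(n, 400)
  p <- br$n_clamp / n
  expect_lt(abs(p - 0.6), 3 * sqrt(0.6 * 0.4 / n) + 0.015)
  # the derived split falls between the two emission means
  expect_gt(attr(ev, "fret_split"), 0.35)
  expect_lt(attr(ev, "fret_split"), 0.8)
})

test_that("count_branches tallies only uncensored outcomes", {
  ev <- tibble::tibble(
    outcome = c(rep("clamp", 30), rep("dissociated", 20), rep(NA, 5)),
    censored = c(rep(FALSE, 50), rep(TRUE, 5))
  )
  br <- count_branches(ev)
  expect_equal(br$n_clamp, 30L)
  expect_equal(br$n_dissoc, 20L)
  empty <- count_branches(ev[0, ])
  expect_equal(c(empty$n_clamp, empty$n_dissoc), c(0L, 0L))
})
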