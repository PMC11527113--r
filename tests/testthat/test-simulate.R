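test_that("identical configs reproduce bit-identical datasets", {
  kin <- binding_kinetics(k_arrival = 0.02, k_dissoc = 0.2, k_clamp = 0.1)
  cfg <- sim_config(kin, n_molecules = 5, seed = 123)
  a <- simulate_binding_experiment(cfg)
  b <- simulate_binding_experiment(cfg)
  expect_identical(a$traces, b$traces)
  expect_identical(a$paths, b$paths)
  # a different seed changes the data
  cfg2 <- sim_config(kin, n_molecules = 5, seed = 124)
  expect_false(identical(simulate_binding_experiment(cfg2)$traces, a$traces))
})

test_that("an absorbing state is never left", {
  kin <- two_state_kinetics(k_unwind = 0.5, k_rewind = 0)
  path <- simulate_ctmc_path(kin, duration = 100, start_state = "unwound",
                             seed = 1)
  expect_equal(nrow(path), 1)
  expect_equal(path$state, "unwound")
  expect_equal(path$t_exit, 100)
  expect_error(simulate_ctmc_path(kin, duration = -1),
               class = "smfret_invalid_parameter")
})

test_that("bound-state exits branch and dwell as the rates dictate", {
  # closed-form oracle: branch P = k2/(k-1 + k2) = 0.6; mean sojourn = 2 s
  kin <- binding_kinetics(k_arrival = 5, k_dissoc = 0.2, k_clamp = 0.3,
                          clamp_exit = 10)
  path <- simulate_ctmc_path(kin, duration = 3e5, seed = 77)
  b <- which(path$state == "bound" & path$t_exit < 3e5)
  expect_gt(length(b), 1e5)
  to_clamp <- path$state[b + 1] == "clamp"
  expect_equal(mean(to_clamp), 0.6, tolerance = 0.01 / 0.6)
  sojourn <- path$t_exit[b] - path$t_entry[b]
  expect_equal(mean(sojourn), 2.0, tolerance = 0.02)
})

test_that("sojourn times are exponential (Kolmogorov-Smirnov at alpha 0.01)", {
  kin <- two_state_kinetics(k_unwind = 0.5, k_rewind = 0.8)
  path <- simulate_ctmc_path(kin, duration = 45000, seed = 42)
  complete <- path[path$t_exit < 45000, ]
  wound <- complete[complete$state == "wound", ]
  d <- wound$t_exit - wound$t_entry
  expect_gt(length(d), 10000)
  p <- stats::ks.test(d, "pexp", rate = 0.5)$p.value
  expect_gt(p, 0.01)
})

test_that("snapshot populations follow one-phase association at every timepoint", {
  kin <- snapshot_kinetics(k_assoc = 0.2, plateau = 0.79, y0 = 0.35)
  cfg <- sim_config(kin, n_molecules = 4000, seed = 31)
  tp <- c(0, 1, 5, 5000) # includes the t=0 and t->infinity limits
  snap <- simulate_snapshot_experiment(cfg, timepoints = tp)
  truth <- one_phase_association(tp, 0.35, 0.79, 0.2)
  for (i in seq_along(tp)) {
    d <- snap[snap$t_min == tp[i] & snap$component != "donor_only", ]
    f <- mean(d$component[!duplicated(d$molecule)] == "unwound")
    n_mol <- length(unique(d$molecule))
    tol <- 3 * sqrt(truth[i] * (1 - truth[i]) / n_mol) + 1e-9
    expect_lt(abs(f - truth[i]), tol + 0.005)
  }
  expect_error(simulate_snapshot_experiment(cfg, numeric(0)),
               class = "smfret_invalid_parameter")
  expect_error(simulate_snapshot_experiment(cfg, c(5, 1)),
               class = "smfret_invalid_parameter")
})

test_that("snapshot unwound probability matches the closed form at t = 5 min", {
  kin <- snapshot_kinetics(k_assoc = 0.2, plateau = 0.79, y0 = 0.35)
  cfg <- sim_config(kin, n_molecules = 5000, seed = 9)
  snap <- simulate_snapshot_experiment(cfg, timepoints = 5)
  # Eq: 0.35 + 0.44 * (1 - exp(-1)) = 0.628
  d <- snap[snap$component != "donor_only", ]
  f <- mean(d$component[!duplicated(d$molecule)] == "unwound")
  expect_equal(f, 0.35 + 0.44 * (1 - exp(-1)), tolerance = 0.02 / 0.63)
})

test_that("binding arrivals are Poisson with the configured rate", {
  sched <- excitation_schedule(
    data.frame(start_frame = 0L, end_frame = 1500L, channel = "donor_ex"), 0.2)
  kin <- binding_kinetics(k_arrival = 0.05, k_dissoc = 20, k_clamp = 0)
  cfg <- sim_config(kin, schedule = sched, n_molecules = 200, seed = 55)
  ts <- simulate_binding_experiment(cfg)
  n_events <- sum(ts$paths$state == "bound")
  # 200 molecules x 300 s x 0.05 /s = 3000 expected (sd ~55); the brief
  # bound occupancy (1/20 s) removes ~0.25% of live time
  expect_lt(abs(n_events - 3000), 165)
})

test_that("ADP-archetype paths never visit the clamp state and dwells average 1/k", {
  kin <- binding_kinetics(k_arrival = 0.05, k_dissoc = 0.204, k_clamp = 0)
  cfg <- sim_config(kin, n_molecules = 60, seed = 6)
  ts <- simulate_binding_experiment(cfg)
  expect_false("clamp" %in% ts$paths$state)
  b <- ts$paths[ts$paths$state == "bound" &
                  ts$paths$t_exit < n_frames(cfg$schedule) * 0.2, ]
  expect_gt(nrow(b), 500)
  expect_equal(mean(b$t_exit - b$t_entry), 1 / 0.204, tolerance = 0.03)
})

test_that("a schedule longer than the state path is a contract violation", {
  kin <- two_state_kinetics(0.5, 0.5)
  cfg <- sim_config(kin, schedule = donor_only_schedule(100), n_molecules = 1,
                    seed = 1)
  short_path <- simulate_ctmc_path(kin, duration = 1, seed = 1)
  expect_error(render_trace(short_path, cfg),
               class = "smfret_contract_violation")
})
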