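test_that("excitation schedules validate their segment structure", {
  expect_s3_class(schedule_cas9_snapshot(), "fret_schedule")
  expect_equal(n_frames(schedule_muts_adp()), 1000)
  expect_equal(n_frames(schedule_muts_atp()), 1500)
  # non-contiguous segments are rejected
  expect_error(
    excitation_schedule(data.frame(start_frame = c(0, 15), end_frame = c(10, 20),
                                   channel = c("donor_ex", "acceptor_ex")), 0.05),
    class = "smfret_invalid_parameter"
  )
  expect_error(
    excitation_schedule(data.frame(start_frame = 0, end_frame = 10,
                                   channel = "donor_ex"), -1),
    class = "smfret_invalid_parameter"
  )
  fr <- schedule_frames(schedule_cas9_snapshot())
  expect_equal(nrow(fr), 20)
  expect_equal(sum(fr$excitation == "donor_ex"), 10)
  expect_equal(fr$time_s[11], 0.5)
})

test_that("compute_fret evaluates the background-corrected proximity ratio", {
  tr <- make_trace(donor = c(400, 500, 500), acceptor = c(600, 500, 500))
  e <- compute_fret(tr)$fret
  expect_equal(e[1], 0.6)
  expect_equal(e[2], 0.5) # equal channels, gamma 1
  # explicit backgrounds and gamma: (500-100)/((500-100) + 2*(500-100)) = 1/3
  e2 <- compute_fret(tr, background_donor = 100, background_acceptor = 100,
                     gamma = 2)$fret
  expect_equal(e2[3], 1 / 3)
  expect_error(compute_fret(tr, gamma = 0), class = "smfret_invalid_parameter")
})

test_that("non-positive corrected total intensity yields NA, not an error", {
  tr <- make_trace(donor = c(10, 400), acceptor = c(10, 600))
  e <- compute_fret(tr, background_donor = 50, background_acceptor = 50)$fret
  expect_true(is.na(e[1]))
  expect_false(is.na(e[2]))
})

test_that("FRET is invariant under joint positive rescaling of channels and backgrounds", {
  set.seed(101)
  for (i in 1:20) {
    d <- runif(30, 100, 900); a <- runif(30, 100, 900)
    bd <- runif(1, 0, 50); ba <- runif(1, 0, 50)
    c0 <- runif(1, 0.1, 10)
    tr1 <- make_trace(d, a)
    tr2 <- make_trace(d * c0, a * c0)
    e1 <- compute_fret(tr1, bd, ba)$fret
    e2 <- compute_fret(tr2, bd * c0, ba * c0)$fret
    expect_equal(e1, e2, tolerance = 1e-12)
  }
})

test_that("noiseless rendering reproduces the generative FRET mean exactly", {
  kin <- two_state_kinetics(0.5, 0, fret_wound = c(0.6, 0),
                            fret_unwound = c(0.3, 0))
  cfg <- sim_config(kin, schedule = donor_only_schedule(50),
                    n_molecules = 1, noise = noiseless(), seed = 3)
  path <- simulate_ctmc_path(kin, duration = 2.5, start_state = "wound",
                             seed = 3)
  tr <- render_trace(path, cfg, seed = 4)
  truth <- frame_states(path, cfg$schedule)
  e <- compute_fret(tr)$fret
  expect_equal(e, ifelse(truth$state == "wound", 0.6, 0.3))
  # intensities split exactly: acceptor = E * total, donor = (1 - E) * total
  wound_frames <- truth$state == "wound"
  expect_true(all(tr$acceptor[wound_frames] == 600))
  expect_true(all(tr$donor[wound_frames] == 400))
})

test_that("acceptor-presence filter separates active from dark acceptors", {
  kin <- two_state_kinetics(0.5, 0.5)
  # active acceptor, noiseless: passes
  cfg <- sim_config(kin, n_molecules = 1, noise = noiseless(), seed = 5)
  ts <- simulate_twostate_experiment(cfg)
  expect_true(acceptor_present(ts$traces, threshold = 100)$acceptor_present)
  # forced-dark acceptor: fails
  cfg2 <- sim_config(kin, n_molecules = 1, noise = noiseless(),
                     photophysics = photophysics_model(inactive_acceptor_fraction = 1),
                     seed = 5)
  ts2 <- simulate_twostate_experiment(cfg2)
  expect_false(acceptor_present(ts2$traces, threshold = 100)$acceptor_present)
  # schedule without acceptor frames is a contract violation
  cfg3 <- sim_config(kin, schedule = donor_only_schedule(20), n_molecules = 1,
                     seed = 5)
  ts3 <- simulate_twostate_experiment(cfg3)
  expect_error(acceptor_present(ts3$traces, threshold = 100),
               class = "smfret_contract_violation")
})

test_that("inactive-acceptor removal matches the binomial expectation", {
  kin <- two_state_kinetics(0.5, 0.5)
  cfg <- sim_config(kin, n_molecules = 5000,
                    photophysics = photophysics_model(inactive_acceptor_fraction = 0.1),
                    seed = 8)
  ts <- simulate_twostate_experiment(cfg)
  keep <- acceptor_present(ts$traces, threshold = 300, background = 50)
  n_removed <- sum(!keep$acceptor_present)
  # binomial mean 500, sd ~21; allow a little over 2 sd
  expect_gt(n_removed, 450)
  expect_lt(n_removed, 550)
  # filtering is non-mutating and subsetting
  filtered <- filter_acceptor_present(ts$traces, threshold = 300, background = 50)
  expect_true(all(unique(filtered$molecule) %in% unique(ts$traces$molecule)))
  expect_lt(length(unique(filtered$molecule)), 5000)
})

test_that("histogram-frame selection takes donor-excitation ordinals 3 to 7", {
  e <- round(runif(10, 0.2, 0.8), 3)
  fret <- tibble::tibble(molecule = 1L, frame = 0:9, time_s = (0:9) * 0.05,
                         fret = e)
  sel <- select_histogram_frames(fret)
  expect_equal(sel$fret, e[3:7])
  # constant trajectory: five copies
  fret2 <- dplyr::mutate(fret, fret = 0.6)
  expect_equal(select_histogram_frames(fret2)$fret, rep(0.6, 5))
  # a missing value inside the window is dropped, not replaced
  fret3 <- fret
  fret3$fret[5] <- NA
  expect_equal(select_histogram_frames(fret3)$fret, e[c(3, 4, 6, 7)])
  # too-short trajectories violate the contract
  expect_error(select_histogram_frames(fret[1:6, ]),
               class = "smfret_contract_violation")
})
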