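test_that("zeroing all sources and mechanics yields a fixed point at the origin", {
  params <- shipped_params()
  params$values[c("kbar_inf1", "k_inh3", "k_inh11", "k_sma1", "k_sma7",
                  "k_sma8", "b0")] <- 0
  params$initial[] <- 0
  mech <- mechanical_input(0.3, tau0 = 0, eps0 = 0.27)
  cfg <- run_config(mech, horizon_years = 5)
  traj <- simulate_case(cfg, params)
  expect_true(all(abs(as.matrix(traj[, species_names()])) < 1e-12))
})

test_that("with k_td = 0 the effective shear stays at its initial value", {
  params <- shipped_params()
  mech <- mechanical_input(0.3, tau0 = 2.23, eps0 = 0.27, k_td = 0)
  traj <- simulate_case(run_config(mech, horizon_years = 6), params)
  expect_equal(traj$tau_bar, rep(2.23, nrow(traj)))
  expect_gt(traj$Ca[nrow(traj)], 0)
})

test_that("trajectories satisfy their structural invariants", {
  trajs <- reference_trajectories()
  params <- shipped_params()
  for (cn in names(trajs)) {
    traj <- trajs[[cn]]
    mech <- attr(traj, "config")$case
    expect_equal(traj$time_years[1], 0)
    expect_true(all(diff(traj$time_years) > 0))
    # stored mechanical series equal the feedback laws applied to Ca(t)
    expect_equal(traj$tau_bar, wss_update(pmax(traj$Ca, 0), mech),
                 tolerance = 1e-12)
    expect_equal(traj$eps_bar, strain_update(pmax(traj$Ca, 0), mech),
                 tolerance = 1e-12)
    # first state equals the configured initial conditions
    expect_equal(unlist(traj[1, species_names()]), params$initial,
                 tolerance = 1e-9)
    # calcification is non-decreasing
    expect_true(all(diff(traj$Ca) >= -1e-8 * max(traj$Ca)))
    # concentrations are non-negative within integrator tolerance
    expect_true(all(as.matrix(traj[, species_names()]) > -1e-12))
  }
})

test_that("the thick case reaches any fixed level no later than the thin case", {
  trajs <- reference_trajectories()
  for (level in c(50, 200, 400)) {
    expect_lte(time_to_threshold(trajs$thick, level),
               time_to_threshold(trajs$thin, level))
  }
})

test_that("threshold crossing interpolates linearly and handles edge cases", {
  synth <- structure(
    data.frame(time_years = 0:23, Ca = 20 * (0:23)),
    class = c("cavd_trajectory", "data.frame"))
  expect_equal(time_to_threshold(synth, 400), 20.0)
  expect_true(is.na(time_to_threshold(synth, 1000)))
  bad <- structure(data.frame(time_years = 0:3, Ca = c(0, 5, 4, 8)),
                   class = c("cavd_trajectory", "data.frame"))
  expect_error(time_to_threshold(bad, 400), "nonmonotone_error")
})

test_that("write/read round trip preserves values and records calibration provenance", {
  traj <- reference_trajectories()$thin
  path <- withr::local_tempfile(fileext = ".csv")
  files <- write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_identical(names(back),
                   c("time_years", species_names(), "tau_bar", "eps_bar"))
  expect_identical(back$Ca, traj$Ca)             # full-precision round trip
  expect_identical(back$NO, traj$NO)
  meta <- attr(back, "metadata")
  expect_identical(meta$calibration$gamma_kc, "calibrated")
  expect_equal(meta$parameters$gamma, shipped_params()$values[["gamma"]])
  expect_identical(meta$case$name, "thin")
})

test_that("identical configuration and parameters give identical output files", {
  params <- shipped_params()
  cfg <- run_config(case_library()$mid, horizon_years = 4)
  t1 <- simulate_case(cfg, params)
  t2 <- simulate_case(cfg, params)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(t1, p1); write_trajectory(t2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("doubling the output grid moves crossing times by less than 0.1 year", {
  params <- shipped_params()
  for (cs in case_library()) {
    c1 <- run_config(cs, output_months = 1)
    c2 <- run_config(cs, output_months = 0.5)
    t1 <- time_to_threshold(simulate_case(c1, params), 400)
    t2 <- time_to_threshold(simulate_case(c2, params), 400)
    expect_lt(abs(t1 - t2), 0.1)
  }
})

test_that("a truncated run restarted from its saved state reproduces the endpoint", {
  params <- shipped_params()
  cs <- case_library()$thin
  full <- reference_trajectories()$thin
  first <- simulate_case(run_config(cs, horizon_years = 10), params)
  saved <- unlist(first[nrow(first), species_names()])
  second <- simulate_case(run_config(cs, horizon_years = 13), params,
                          init_state = saved)
  ca_restart <- second$Ca[nrow(second)]
  ca_full <- full$Ca[nrow(full)]
  expect_lt(abs(ca_restart - ca_full) / ca_full, 0.005)
})

test_that("solver accepts the solution under tolerance halving", {
  params <- shipped_params()
  cfg <- run_config(case_library()$thin, check_tolerance = TRUE)
  traj <- simulate_case(cfg, params)
  rel <- attr(traj, "solver")$tolerance_check_rel_change
  expect_lt(rel, 0.005)
})

test_that("invalid configurations are rejected with named errors", {
  expect_error(run_config(case_library()$thin, horizon_years = -1),
               "config_error")
  expect_error(run_config(case_library()$thin, threshold = 0), "config_error")
  expect_error(run_config(case_library()$thin, rtol = 0), "config_error")
})
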