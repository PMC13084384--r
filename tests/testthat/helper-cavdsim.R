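# Shared lazily-computed fixtures: the shipped parameter set and the three
# full-horizon reference trajectories, each simulated once per test run.

.fixture_env <- new.env(parent = emptyenv())

shipped_params <- function() {
  if (is.null(.fixture_env$params))
    .fixture_env$params <- load_parameters()
  .fixture_env$params
}

reference_trajectories <- function() {
  if (is.null(.fixture_env$trajs)) {
    params <- shipped_params()
    .fixture_env$trajs <- lapply(case_library(), function(cs)
      simulate_case(run_config(cs), params))
  }
  .fixture_env$trajs
}

# value of a species at the output point closest to a given year
species_at <- function(traj, species, years) {
  d <- as.data.frame(traj)
  d[which.min(abs(d$time_years - years)), species]
}

# random non-negative state vector on the model's characteristic scales
random_state <- function(rng_draw) {
  sp <- species_names()
  scale <- c(rep(1e-9, 7), rep(1e-8, 6), rep(1e-8, 11), 100)
  st <- stats::setNames(rng_draw(length(sp)) * scale, sp)
  st
}
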