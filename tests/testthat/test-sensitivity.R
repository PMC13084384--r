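test_that("the scan inventory covers exactly the 73 model quantities", {
  inv <- sensitivity_inventory(shipped_params())
  expect_identical(nrow(inv), 73L)
  expect_identical(sum(inv$class == "mechanical input"), 2L)
  expect_identical(sum(inv$class == "coupling parameter"), 5L)
  expect_identical(sum(inv$class == "rate constant"), 66L)
  expect_identical(sum(grepl("^k(bar)?_inf", inv$quantity)), 12L)
  expect_identical(sum(grepl("^k_inh", inv$quantity)), 15L)
  expect_identical(sum(grepl("^k_sma", inv$quantity)) + 2L, 39L) # + gamma, k_c
  expect_false(any(c("k_td", "tau_ref") %in% inv$quantity))
})

test_that("a quantity no RHS term reads reports exactly zero change", {
  params <- shipped_params()
  params$values[["k_dead"]] <- 1e-5
  params$units[["k_dead"]] <- "1/s"
  params$source[["k_dead"]] <- "calibrated"
  expect_true("k_dead" %in% parameter_audit(params)$unused)
  cfg <- run_config(case_library()$thin, horizon_years = 2)
  rep <- sensitivity_scan(params, cases = case_library()["thin"],
                          config = cfg,
                          quantities = data.frame(quantity = "k_dead",
                                                  class = "rate constant"))
  expect_identical(rep$rel_plus, 0)
  expect_identical(rep$rel_minus, 0)
  expect_false(rep$failed)
})

test_that("scan rows match directly computed perturbed runs", {
  params <- shipped_params()
  cfg <- run_config(case_library()$thin, horizon_years = 3)
  rep <- sensitivity_scan(params, cases = case_library()["thin"],
                          config = cfg,
                          quantities = data.frame(quantity = "gamma",
                                                  class = "rate constant"))
  up <- params; up$values[["gamma"]] <- up$values[["gamma"]] * 1.1
  ca_up <- simulate_case(cfg, up)$Ca
  ca_up <- ca_up[length(ca_up)]
  expect_equal(rep$ca_plus, ca_up)
  expect_equal(rep$rel_plus, abs(ca_up - rep$ca_base) / rep$ca_base)
})

test_that("small perturbations respond symmetrically within a factor of two", {
  params <- shipped_params()
  cfg <- run_config(case_library()$thin)
  base <- reference_trajectories()$thin
  ca0 <- base$Ca[nrow(base)]
  for (q in c("gamma", "kbar_inf1", "k_inh9", "k_sma8")) {
    rel <- vapply(c(1.01, 0.99), function(f) {
      p <- params; p$values[[q]] <- p$values[[q]] * f
      tr <- simulate_case(cfg, p)
      abs(tr$Ca[nrow(tr)] - ca0) / ca0
    }, 0)
    expect_lt(max(rel) / min(rel), 2)
  }
})

test_that("failed perturbed runs are recorded, not dropped", {
  params <- shipped_params()
  params$values[["xi"]] <- 0.95   # +10% pushes xi above its upper bound
  cfg <- run_config(case_library()$thin, horizon_years = 2)
  rep <- sensitivity_scan(params, cases = case_library()["thin"],
                          config = cfg,
                          quantities = data.frame(quantity = "xi",
                                                  class = "coupling parameter"))
  expect_true(rep$failed)
  expect_true(is.na(rep$ca_plus))
  expect_false(is.na(rep$ca_minus))
})

test_that("ranking is deterministic, order-invariant, and respects the cutoff", {
  df <- data.frame(
    quantity = c("a", "b", "c", "a", "b", "c"),
    class = "rate constant",
    case = rep(c("x", "y"), each = 3),
    perturbation = 0.1, ca_base = 100,
    ca_plus = 1, ca_minus = 1,
    rel_plus = 1, rel_minus = 1,
    rel_max = c(0.05, 0.2, 0.12, 0.07, 0.01, 0.3),
    failed = FALSE)
  rep <- structure(df, class = c("sensitivity_report", "data.frame"))
  rk <- sensitivity_rank(rep, cutoff = 0.10)
  expect_identical(rk$quantity, c("c", "b", "a"))
  expect_identical(attr(rk, "n_above"), 2L)
  shuffled <- structure(df[c(4, 2, 6, 1, 5, 3), ],
                        class = c("sensitivity_report", "data.frame"))
  expect_identical(sensitivity_rank(shuffled, 0.10)$quantity, rk$quantity)
  expect_identical(attr(sensitivity_rank(rep, 1.0), "n_above"), 0L)
})
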