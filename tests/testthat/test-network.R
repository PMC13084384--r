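zero_state <- function() stats::setNames(numeric(25), species_names())

test_that("the generated system covers all species with a reported equation count", {
  sys <- ode_system()
  expect_identical(sys$species, species_names())
  expect_identical(sys$n_equations, 25L)
  lines <- capture.output(dump_odes(sys))
  expect_length(lines, 26L)  # header + one equation per species
  expect_match(lines[1], "25 species equations")
  expect_match(lines[grep("d\\[LDL\\]", lines)], "k_inf1\\(t\\)")
  expect_match(lines[grep("d\\[Ca\\]", lines)], "k_sma26\\(t\\)\\*\\[pS3n\\]")
})

test_that("at an empty state only zeroth-order sources fire, with Eq-8 shear damping", {
  params <- shipped_params()
  d <- rhs_inflammation(zero_state(), params, tau = 2, tau_ref = 2)
  expect_equal(unname(d[["LDL"]]), params$values[["kbar_inf1"]] / 2)
  expect_true(all(d[setdiff(names(d), "LDL")] == 0))
  # zero shear doubles the LDL influx relative to the reference shear
  d0 <- rhs_inflammation(zero_state(), params, tau = 0)
  expect_equal(unname(d0[["LDL"]]), 2 * unname(d[["LDL"]]))
})

test_that("steady LDL level solves k_inf1 = (k_inf2 + k_inf3) * LDL", {
  params <- shipped_params()
  tau <- 1.7
  k1 <- shear_modulated_rate(params$values[["kbar_inf1"]], tau, 2)
  st <- zero_state()
  st[["LDL"]] <- k1 / (params$values[["k_inf2"]] + params$values[["k_inf3"]])
  d <- rhs_inflammation(st, params, tau = tau, tau_ref = 2)
  expect_equal(unname(d[["LDL"]]), 0, tolerance = 1e-25)
})

test_that("NO balance reduces to flow-induced production when NO and NO-sGC are zero", {
  params <- shipped_params()
  st <- zero_state(); st[["sGC"]] <- 1e-7
  for (tau in c(0, 1.33, 2.23)) {
    d <- rhs_no_pkg(st, params, tau = tau)
    kno <- no_production_rate(tau, params$values[["b0"]], params$values[["b1"]])
    expect_equal(unname(d[["NO"]]), kno)
  }
})

test_that("the binding/unbinding pair conserves total sGC", {
  params <- shipped_params()
  # silence synthesis, degradation, and complex decay; keep binding/unbinding
  for (k in c("k_inh3", "k_inh4", "k_inh5", "k_inh14"))
    params$values[[k]] <- 0
  st <- zero_state()
  st[c("NO", "sGC", "NOsGC")] <- c(4e-9, 8e-8, 3e-8)
  d <- rhs_no_pkg(st, params, tau = 1.5)
  expect_equal(unname(d[["sGC"]] + d[["NOsGC"]]), 0, tolerance = 1e-25)
})

test_that("without active TGF-beta or pSMAD there is no phosphorylation or calcification", {
  params <- shipped_params()
  st <- zero_state()
  st[c("S2c", "S3c", "S2n", "S3n", "R")] <- c(1e-7, 1e-7, 1e-8, 1e-8, 3e-10)
  d <- rhs_smad(st, params, eps = 0.27)
  for (sp in c("pS2c", "pS3c", "pS2n", "pS3n", "pS3i", "Ca"))
    expect_equal(unname(d[[sp]]), 0)
})

test_that("inhibited pSMAD3 is produced only through PKG-dependent conversion", {
  params <- shipped_params()
  st <- zero_state()
  st[c("pS3c", "pS3n")] <- c(1e-9, 2e-9)
  d <- rhs_smad(st, params, eps = 0.25)   # PKGa = 0
  expect_equal(unname(d[["pS3i"]]), 0)
  st[["PKGa"]] <- 5e-7
  d2 <- rhs_smad(st, params, eps = 0.25)
  expect_gt(unname(d2[["pS3i"]]), 0)
})

test_that("calcium production scales by (1+h_e) across strain levels", {
  params <- shipped_params()
  st <- zero_state()
  st[c("pS2n", "pS3n")] <- c(3e-8, 2e-8)
  d1 <- rhs_smad(st, params, eps = 0.27)
  d2 <- rhs_smad(st, params, eps = 0.236)
  ratio <- (1 + strain_magnification(0.27)) /
           (1 + strain_magnification(0.236))
  expect_equal(unname(d1[["Ca"]] / d2[["Ca"]]), ratio, tolerance = 1e-12)
  expect_gt(d1[["Ca"]], 0)
})

test_that("assembled RHS matches a finite-difference step of the integrator", {
  params <- shipped_params()
  mech <- case_library()$thin
  st <- params$initial
  st[c("LDL", "oxLDL", "mono", "macro", "foam", "TGFb_lat", "TGFb_act")] <-
    c(1e-9, 5e-10, 2e-10, 4e-10, 8e-10, 3e-10, 1e-13)
  st[c("NO", "NOsGC", "cGMP", "PKGa")] <- c(3e-9, 2e-10, 2e-9, 3e-7)
  st[c("RC", "pS2c", "pS3c", "pS2n", "pS3n", "pS3i", "S2n", "S3n")] <-
    c(8e-13, 2e-9, 1e-9, 6e-9, 4e-9, 1e-7, 5e-9, 5e-9)
  st[["Ca"]] <- 30
  d <- assemble_rhs(st, params, mech)
  sys <- cavdsim:::.get_sys()
  rhs <- cavdsim:::.make_rhs(sys, params, mech)
  # fast path used by the solver agrees with the reference assembly
  expect_equal(rhs(0, st, NULL)[[1]], unname(d), tolerance = 1e-12,
               ignore_attr = TRUE)
  # one tiny explicit step reproduces the derivative to first order
  delta <- 1e-3
  out <- deSolve::ode(st, c(0, delta), rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-20)
  fd <- (out[2, species_names()] - out[1, species_names()]) / delta
  slack <- c(rep(1e-19, 24), 1e-10)  # per-unit-class absolute slack
  err <- abs(unname(fd) - unname(d))
  expect_true(all(err <= 1e-3 * abs(unname(d)) + slack))
})

test_that("mechanics enter only through the five coupled rate constants", {
  params <- shipped_params()
  set.seed(11)
  st <- random_state(stats::runif)
  d1 <- rhs_inflammation(st, params, tau = 0.9)
  d2 <- rhs_inflammation(st, params, tau = 2.4)
  changed <- names(d1)[abs(d1 - d2) > 0]
  expect_true(all(changed %in% c("LDL", "mono")))  # k_inf1 and k_inf5 targets
  n1 <- rhs_no_pkg(st, params, tau = 0.9)
  n2 <- rhs_no_pkg(st, params, tau = 2.4)
  expect_identical(names(n1)[abs(n1 - n2) > 0], "NO")  # k_NO target
  s1 <- rhs_smad(st, params, eps = 0.21)
  s2 <- rhs_smad(st, params, eps = 0.26)
  expect_identical(names(s1)[abs(s1 - s2) > 0], "Ca")  # k_sma26/27 targets
})

test_that("zeroing the NO module leaves inflammation derivatives unchanged", {
  params <- shipped_params()
  set.seed(12)
  st <- random_state(stats::runif)
  zeroed <- params
  zeroed$values[grep("^k_inh|^b0", names(zeroed$values))] <- 0
  d1 <- rhs_inflammation(st, params, tau = 1.8)
  d2 <- rhs_inflammation(st, zeroed, tau = 1.8)
  expect_identical(d1, d2)
})

test_that("no flux leaves an empty pool and calcification production is non-negative", {
  params <- shipped_params()
  mech <- case_library()$thin
  set.seed(42)
  for (i in 1:40) {
    st <- random_state(stats::runif)
    empty <- sample(species_names(), 8)
    st[empty] <- 0
    d <- assemble_rhs(st, params, mech)
    expect_true(all(d[empty] >= 0),
                info = paste("outflux from empty pool at draw", i))
    expect_gte(unname(d[["Ca"]]), 0)
  }
})

test_that("negative states beyond tolerance are rejected", {
  params <- shipped_params()
  st <- zero_state(); st[["LDL"]] <- -1e-3
  expect_error(assemble_rhs(st, params, case_library()$thin),
               "negative species")
})
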