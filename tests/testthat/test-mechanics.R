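const_field <- function(value, n_nodes = 5, n_times = 11,
                        quantity = "shear", dA = NULL) {
  tt <- seq(0, 1, length.out = n_times)
  grid <- expand.grid(node = seq_len(n_nodes), it = seq_len(n_times))
  if (is.null(dA)) dA <- rep(1, n_nodes)
  field_series(grid$node, tt[grid$it], rep(value, nrow(grid)),
               dA[grid$node], quantity = quantity)
}

test_that("both averages reduce to the constant on constant fields", {
  for (c0 in c(0.5, 2.2)) {
    f <- const_field(c0, n_nodes = 7, n_times = 23,
                     dA = runif(7, 0.5, 2))
    expect_equal(sa_wss(f), c0, tolerance = 1e-12)
    expect_equal(avg_max_strain(const_field(c0, quantity = "strain")), c0,
                 tolerance = 1e-12)
  }
})

test_that("linear-in-time shear averages to half its end value", {
  n_times <- 2001
  tt <- seq(0, 1, length.out = n_times)
  c0 <- 3.4
  grid <- expand.grid(node = 1:4, it = seq_len(n_times))
  f <- field_series(grid$node, tt[grid$it], c0 * tt[grid$it],
                    rep(1, 4)[grid$node], quantity = "shear")
  expect_equal(sa_wss(f), c0 / 2, tolerance = 1e-9)
})

test_that("two-node half-sine strain averages to 2c/pi", {
  n_times <- 4001
  tt <- seq(0, 1, length.out = n_times)
  c0 <- 0.31
  vals <- c(rep(0, n_times), c0 * sin(pi * tt))
  f <- field_series(rep(1:2, each = n_times), rep(tt, 2), vals,
                    rep(1, 2 * n_times), quantity = "strain")
  expect_equal(avg_max_strain(f), 2 * c0 / pi, tolerance = 1e-6)
})

test_that("synthetic fixtures match a dense brute-force quadrature oracle", {
  fx <- generate_synthetic_fields(n_nodes = 20, n_times = 2001, seed = 0)
  dense <- generate_synthetic_fields(n_nodes = 20, n_times = 40001, seed = 0)

  # independent oracle: midpoint Riemann sum over the dense sampling
  riemann <- function(field, reduce) {
    m <- cavdsim:::.side_matrix(field, "ventricular")
    y <- reduce(m)
    mid <- (y[-1] + y[-length(y)]) / 2
    sum(mid * diff(m$t)) / (max(m$t) - min(m$t))
  }
  wss_oracle <- riemann(dense$shear,
                        function(m) drop(crossprod(m$dA, m$V)) / sum(m$dA))
  strain_oracle <- riemann(dense$strain,
                           function(m) apply(abs(m$V), 2, max))

  expect_lt(abs(sa_wss(fx$shear) - wss_oracle) / wss_oracle, 1e-6)
  expect_lt(abs(avg_max_strain(fx$strain) - strain_oracle) / strain_oracle,
            1e-6)
})

test_that("default generator magnitudes bracket the physiological range", {
  fx <- generate_synthetic_fields(n_nodes = 40, n_times = 801, seed = 0)
  expect_gt(sa_wss(fx$shear), 1); expect_lt(sa_wss(fx$shear), 2.5)
  expect_gt(avg_max_strain(fx$strain), 0.2)
  expect_lt(avg_max_strain(fx$strain), 0.3)
})

test_that("generator is deterministic and sa_wss is linear in amplitude", {
  a <- generate_synthetic_fields(8, 101, seed = 7)
  b <- generate_synthetic_fields(8, 101, seed = 7)
  expect_identical(as.data.frame(a$shear), as.data.frame(b$shear))
  expect_identical(as.data.frame(a$strain), as.data.frame(b$strain))
  scaled <- generate_synthetic_fields(8, 101, seed = 7, tau_amplitude = 14)
  expect_equal(sa_wss(scaled$shear), 2 * sa_wss(a$shear), tolerance = 1e-12)
  # positive homogeneity and monotonicity of the strain statistic
  up <- a$strain; up$value <- up$value * 3
  up <- field_series(up$node_id, up$time_s, up$value, up$dA_cm2, up$side,
                     quantity = "strain")
  expect_equal(avg_max_strain(up), 3 * avg_max_strain(a$strain),
               tolerance = 1e-12)
  bigger <- a$strain; bigger$value <- bigger$value + 0.01
  bigger <- field_series(bigger$node_id, bigger$time_s, bigger$value,
                         bigger$dA_cm2, bigger$side, quantity = "strain")
  expect_gt(avg_max_strain(bigger), avg_max_strain(a$strain))
})

test_that("halving the time step changes the statistics by less than 1e-4", {
  coarse <- generate_synthetic_fields(15, 401, seed = 0)
  fine <- generate_synthetic_fields(15, 801, seed = 0)
  expect_lt(abs(sa_wss(fine$shear) - sa_wss(coarse$shear)) /
              sa_wss(fine$shear), 1e-4)
  expect_lt(abs(avg_max_strain(fine$strain) - avg_max_strain(coarse$strain)) /
              avg_max_strain(fine$strain), 1e-4)
})

test_that("CSV round trip and the reduction to a mechanical input work", {
  fx <- generate_synthetic_fields(6, 51, seed = 3)
  shear_path <- withr::local_tempfile(fileext = ".csv")
  strain_path <- withr::local_tempfile(fileext = ".csv")
  write_field_series(fx$shear, shear_path)
  write_field_series(fx$strain, strain_path)
  shear2 <- read_field_series(shear_path, "shear")
  strain2 <- read_field_series(strain_path, "strain")
  expect_equal(sa_wss(shear2), sa_wss(fx$shear), tolerance = 1e-12)
  mech <- mechanical_input_from_fields(shear2, strain2, thickness_mm = 0.4)
  expect_s3_class(mech, "mechanical_input")
  expect_equal(mech$tau0, sa_wss(fx$shear), tolerance = 1e-12)
  expect_equal(mech$eps0, avg_max_strain(fx$strain), tolerance = 1e-12)
})

test_that("degenerate fields are rejected with named errors", {
  expect_error(field_series(integer(0), numeric(0), numeric(0), numeric(0)),
               "empty_field_error")
  f <- const_field(1)
  expect_error(sa_wss(f, side = "aortic"), "empty_field_error")
  expect_error(field_series(1:2, c(0, 1), c(1, 1), c(0, 0)), "positive")
  expect_error(read_field_series(tempfile(), "shear"), "field_io_error")
})
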