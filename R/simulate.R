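# Long-horizon stiff integration of the coupled system. Internal time unit
# is seconds (the rate constants are per-second); trajectories are reported
# in years on a monthly output grid by default.

.YEAR_S <- 365.25 * 86400
.MONTH_S <- .YEAR_S / 12

#' Simulation run configuration
#'
#' @param case A [mechanical_input()] describing the leaflet case.
#' @param horizon_years Simulation horizon in years (default 23).
#' @param output_months Output grid spacing in months (default 1).
#' @param threshold High-risk Agatston threshold (default 400).
#' @param rtol Relative solver tolerance (default 1e-6).
#' @param atol_scale Absolute tolerances are `atol_scale` times each
#'   species' characteristic magnitude (default 1e-6).
#' @param method deSolve integrator (default `"lsoda"`, an adaptive
#'   stiff/non-stiff switching method).
#' @param check_tolerance If `TRUE`, re-integrate with both tolerances
#'   halved and reject the solution if the terminal calcification changes
#'   by 0.5% or more.
#' @param params_path Optional parameter-file path recorded with the run.
#' @param side Leaflet side whose SA-WSS feeds the model (metadata).
#' @return A `run_config` object.
#' @export
run_config <- function(case, horizon_years = 23, output_months = 1,
                       threshold = 400, rtol = 1e-6, atol_scale = 1e-6,
                       method = "lsoda", check_tolerance = FALSE,
                       params_path = NULL, side = "ventricular") {
  stopifnot(inherits(case, "mechanical_input"))
  if (!is.numeric(horizon_years) || horizon_years <= 0)
    stop("config_error: horizon_years must be positive", call. = FALSE)
  if (!is.numeric(threshold) || threshold <= 0)
    stop("config_error: threshold must be positive", call. = FALSE)
  if (!is.numeric(output_months) || output_months <= 0)
    stop("config_error: output_months must be positive", call. = FALSE)
  if (rtol <= 0 || atol_scale <= 0)
    stop("config_error: solver tolerances must be positive", call. = FALSE)
  structure(list(case = case, horizon_years = horizon_years,
                 output_months = output_months, threshold = threshold,
                 rtol = rtol, atol_scale = atol_scale, method = method,
                 check_tolerance = isTRUE(check_tolerance),
                 params_path = params_path, side = side),
            class = "run_config")
}

# characteristic magnitudes for per-species absolute tolerances
.species_scales <- function() {
  sp <- species_names()
  scale <- stats::setNames(rep(1e-9, length(sp)), sp)
  scale[c("cGMP", "PKG", "PKGa", "S2c", "S3c", "S2n", "S3n",
          "pS2c", "pS3c", "pS2n", "pS3n", "pS3i")] <- 1e-8
  scale[["Ca"]] <- 1
  scale
}

# Closure evaluated by the integrator. Inlines the coupling laws for speed;
# a regression test pins it against the reference assemble_rhs().
.make_rhs <- function(sys, params, mech) {
  v <- params$values
  k_base <- ifelse(sys$k_names %in% .dynamic_k, 0, v[sys$k_names])
  k_base <- unname(k_base)
  j1 <- which(sys$k_names == "k_inf1")
  j5 <- which(sys$k_names == "k_inf5")
  jno <- which(sys$k_names == "k_NO")
  j26 <- which(sys$k_names == "k_sma26")
  j27 <- which(sys$k_names == "k_sma27")
  i_ca <- match("Ca", sys$species)
  Smat <- sys$Smat; i1 <- sys$i1; i2 <- sys$i2
  kb1 <- v[["kbar_inf1"]]; kb5 <- v[["kbar_inf5"]]
  b0 <- v[["b0"]]; b1 <- v[["b1"]]
  a0 <- v[["a0"]]; a1 <- v[["a1"]]; xi <- v[["xi"]]
  g_kc <- v[["gamma"]] * v[["k_c"]]
  tau0 <- mech$tau0; k_td <- mech$k_td; tau_ref <- mech$tau_ref
  inv_eps0 <- 1 / mech$eps0
  function(t, y, p) {
    ca <- if (y[i_ca] > 0) y[i_ca] else 0
    tau <- tau0 * exp(-k_td * ca)
    eps <- (0.2 * ca + 1) / (ca + inv_eps0)
    k <- k_base
    f <- 1 / (1 + tau / tau_ref)
    k[j1] <- kb1 * f
    k[j5] <- kb5 * f
    k[jno] <- b0 * tau / (b1 + tau)
    k26 <- g_kc * (1 + a0 * (exp(a1 * eps) - 1))
    k[j26] <- k26
    k[j27] <- xi * k26
    s <- c(1, pmax(y, 0))
    list(drop(Smat %*% (k * s[i1] * s[i2])))
  }
}

.integrate <- function(config, params, y0, times_s) {
  sys <- .get_sys()
  rhs <- .make_rhs(sys, params, config$case)
  atol <- config$atol_scale * .species_scales()
  out <- deSolve::ode(y = y0, times = times_s, func = rhs, parms = NULL,
                      method = config$method, rtol = config$rtol,
                      atol = atol, maxsteps = 100000)
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0)
    stop("integration_error: solver failed with istate = ", istate[1],
         " for case '", config$case$name, "' (try tighter tolerances or a",
         " different method)", call. = FALSE)
  if (nrow(out) < length(times_s))
    stop("integration_error: integration stopped early at t = ",
         max(out[, "time"]) / .YEAR_S, " years for case '",
         config$case$name, "'", call. = FALSE)
  list(out = out, istate = istate)
}

#' Simulate one leaflet case over the configured horizon
#'
#' Integrates the coupled inflammation / NO / SMAD / calcification system
#' from the configured initial concentrations with an adaptive
#' stiff-capable solver, evaluating the quasi-steady mechanical feedback
#' laws continuously inside the right-hand side.
#'
#' @param config A [run_config()].
#' @param params A `cavd_parameters` set (default: the shipped file, or
#'   `config$params_path` when set).
#' @param init_state Optional replacement initial state (named over
#'   [species_names()]), e.g. to restart a saved trajectory.
#' @return A `cavd_trajectory`: data frame with `time_years`, one column
#'   per species, and the effective `tau_bar` (Pa) and `eps_bar` series;
#'   attributes carry the config, solver statistics and calibration
#'   provenance.
#' @export
simulate_case <- function(config, params = NULL, init_state = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(params)) params <- load_parameters(config$params_path)
  if (isTRUE(params$calibration$needs_calibration) ||
      any(is.na(params$values[c("gamma", "k_c")])))
    stop("parameter_validation: gamma/k_c are unset; run calibrate_gamma_kc()",
         call. = FALSE)
  .validate_parameter_values(params$values)
  y0 <- if (is.null(init_state)) params$initial else {
    stopifnot(all(species_names() %in% names(init_state)))
    init_state[species_names()]
  }
  horizon_s <- config$horizon_years * .YEAR_S
  dt <- config$output_months * .MONTH_S
  times_s <- unique(c(seq(0, horizon_s, by = dt), horizon_s))

  res <- .integrate(config, params, y0, times_s)
  out <- res$out

  tol_check <- NA_real_
  if (config$check_tolerance) {
    cfg2 <- config
    cfg2$rtol <- config$rtol / 2
    cfg2$atol_scale <- config$atol_scale / 2
    cfg2$check_tolerance <- FALSE
    out2 <- .integrate(cfg2, params, y0, times_s)$out
    ca1 <- out[nrow(out), "Ca"]; ca2 <- out2[nrow(out2), "Ca"]
    tol_check <- abs(ca1 - ca2) / max(abs(ca2), .Machine$double.eps)
    if (tol_check >= 0.005)
      stop("tolerance_error: halving solver tolerances changes terminal ",
           "calcification by ", signif(100 * tol_check, 3),
           "% (>= 0.5%); tighten rtol/atol_scale", call. = FALSE)
  }

  ca <- pmax(out[, "Ca"], 0)
  traj <- data.frame(time_years = out[, "time"] / .YEAR_S,
                     out[, species_names(), drop = FALSE],
                     tau_bar = wss_update(ca, config$case),
                     eps_bar = strain_update(ca, config$case),
                     check.names = FALSE)
  structure(traj,
            class = c("cavd_trajectory", "data.frame"),
            config = config,
            params_values = params$values,
            calibration = params$calibration,
            solver = list(method = config$method, rtol = config$rtol,
                          atol_scale = config$atol_scale,
                          istate = res$istate,
                          tolerance_check_rel_change = tol_check))
}

#' First crossing time of a calcification threshold
#'
#' Linear interpolation between the bracketing output points of a
#' trajectory whose calcification is (as the model guarantees)
#' non-decreasing.
#'
#' @param traj A `cavd_trajectory`.
#' @param threshold Agatston threshold (default 400, the clinically defined
#'   high-risk level).
#' @return Crossing time in years, or `NA_real_` if the threshold is never
#'   reached within the horizon.
#' @export
time_to_threshold <- function(traj, threshold = 400) {
  stopifnot(inherits(traj, "cavd_trajectory"), threshold > 0)
  ca <- traj$Ca
  tol <- max(1e-8 * max(ca, 1), 1e-12)
  if (any(diff(ca) < -tol))
    stop("nonmonotone_error: calcification decreases along the trajectory ",
         "(right-hand-side defect)", call. = FALSE)
  idx <- which(ca >= threshold)[1]
  if (is.na(idx)) return(NA_real_)
  if (idx == 1L) return(traj$time_years[1])
  t0 <- traj$time_years[idx - 1L]; t1 <- traj$time_years[idx]
  c0 <- ca[idx - 1L]; c1 <- ca[idx]
  t0 + (threshold - c0) / (c1 - c0) * (t1 - t0)
}

#' Write a trajectory and its run metadata
#'
#' Writes the trajectory as CSV (full precision, one row per output time,
#' one column per species plus the two effective mechanical series) and a
#' JSON metadata sidecar (`<path minus .csv>_meta.json`) recording the
#' parameters, case, solver statistics and calibration provenance.
#'
#' @param traj A `cavd_trajectory`.
#' @param path CSV output path.
#' @return Named list of the two file paths, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "cavd_trajectory"))
  df <- as.data.frame(traj)
  fmt <- vapply(df, function(col) sprintf("%.17g", col),
                character(nrow(df)))
  fmt <- matrix(fmt, nrow = nrow(df), dimnames = list(NULL, names(df)))
  utils::write.table(fmt, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  cfg <- attr(traj, "config")
  meta <- list(
    case = cfg$case[c("name", "thickness_mm", "tau0", "eps0", "k_td",
                      "tau_ref")],
    run = list(horizon_years = cfg$horizon_years,
               output_months = cfg$output_months,
               threshold = cfg$threshold, side = cfg$side),
    solver = attr(traj, "solver")[c("method", "rtol", "atol_scale",
                                    "tolerance_check_rel_change")],
    parameters = as.list(attr(traj, "params_values")),
    calibration = attr(traj, "calibration"))
  meta_path <- sub("\\.csv$", "", path)
  meta_path <- paste0(meta_path, "_meta.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(list(trajectory = path, metadata = meta_path))
}

#' Read a trajectory written by [write_trajectory()]
#' @param path CSV path.
#' @return A `cavd_trajectory` data frame (metadata attributes restored
#'   from the sidecar when present).
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta_path <- paste0(sub("\\.csv$", "", path), "_meta.json")
  traj <- structure(df, class = c("cavd_trajectory", "data.frame"))
  if (file.exists(meta_path))
    attr(traj, "metadata") <- jsonlite::read_json(meta_path,
                                                  simplifyVector = TRUE)
  traj
}

#' @export
print.cavd_trajectory <- function(x, ...) {
  cfg <- attr(x, "config")
  nm <- if (!is.null(cfg)) cfg$case$name else "?"
  cat(sprintf("<cavd_trajectory> case '%s': %d output points over %.3g years, terminal Ca = %.4g Agatston\n",
              nm, nrow(x), max(x$time_years), x$Ca[nrow(x)]))
  invisible(x)
}
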