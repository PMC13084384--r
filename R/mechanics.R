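# Reduction of nodal shear/strain time series from a fluid-structure
# simulation of one cardiac cycle into the two averaged mechanical inputs
# of the signaling model, plus a synthetic field generator so this stage is
# testable without a flow solver.

#' Construct a nodal field time series
#'
#' Holds one scalar field (shear magnitude in Pa, or the magnitude of the
#' maximum principal strain, dimensionless) sampled at mesh nodes over one
#' cardiac cycle. Every node must be sampled on the same strictly
#' increasing time grid spanning the cycle, and carries a constant area
#' weight.
#'
#' @param node_id Integer/character node identifiers (one per row).
#' @param time_s Sample times in seconds.
#' @param value Field values (Pa for shear, dimensionless for strain).
#' @param dA_cm2 Per-node area weights in cm^2 (constant per node).
#' @param side Leaflet side label: `"ventricular"` or `"aortic"`.
#' @param quantity `"shear"` or `"strain"`.
#' @return A `field_series` object (a validated data frame).
#' @export
field_series <- function(node_id, time_s, value, dA_cm2,
                         side = "ventricular",
                         quantity = c("shear", "strain")) {
  quantity <- match.arg(quantity)
  if (length(node_id) == 0L || length(time_s) == 0L)
    stop("empty_field_error: field series has no samples", call. = FALSE)
  df <- data.frame(node_id = node_id, time_s = time_s, value = value,
                   dA_cm2 = dA_cm2, side = side,
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$time_s)) || any(!is.finite(df$value)) ||
      any(!is.finite(df$dA_cm2)))
    stop("field_error: non-finite entries in field series", call. = FALSE)
  if (any(df$dA_cm2 <= 0))
    stop("field_error: area weights must be positive", call. = FALSE)
  if (!all(df$side %in% c("ventricular", "aortic")))
    stop("field_error: side must be 'ventricular' or 'aortic'",
         call. = FALSE)
  for (s in unique(df$side)) {
    sub <- df[df$side == s, ]
    tt <- sort(unique(sub$time_s))
    if (length(tt) < 2L)
      stop("field_error: need at least two time samples per side",
           call. = FALSE)
    counts <- table(sub$node_id)
    if (length(unique(counts)) != 1L || unique(counts) != length(tt))
      stop("field_error: every node must be sampled at every time",
           call. = FALSE)
    w <- tapply(sub$dA_cm2, sub$node_id, function(x) length(unique(x)))
    if (any(w != 1L))
      stop("field_error: area weight must be constant per node",
           call. = FALSE)
  }
  structure(df, class = c("field_series", "data.frame"),
            quantity = quantity)
}

#' Read a field series from CSV
#'
#' Expects the plain tabular exchange format with header
#' `node_id,time_s,value,dA_cm2,side` -- one file per quantity (per side,
#' or with both sides stacked).
#'
#' @param path CSV path.
#' @param quantity `"shear"` or `"strain"`.
#' @return A [field_series()] object.
#' @export
read_field_series <- function(path, quantity = c("shear", "strain")) {
  quantity <- match.arg(quantity)
  if (!file.exists(path))
    stop("field_io_error: file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("node_id", "time_s", "value", "dA_cm2", "side")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("field_io_error: missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  field_series(df$node_id, df$time_s, df$value, df$dA_cm2, df$side,
               quantity = quantity)
}

#' Write a field series to CSV
#' @param field A [field_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_field_series <- function(field, path) {
  utils::write.csv(as.data.frame(field)[, c("node_id", "time_s", "value",
                                            "dA_cm2", "side")],
                   path, row.names = FALSE)
  invisible(path)
}

.side_matrix <- function(field, side) {
  sub <- field[field$side == side, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("empty_field_error: no samples for side '", side, "'",
         call. = FALSE)
  tt <- sort(unique(sub$time_s))
  nodes <- sort(unique(sub$node_id))
  o <- order(match(sub$node_id, nodes), sub$time_s)
  V <- matrix(sub$value[o], nrow = length(nodes), ncol = length(tt),
              byrow = TRUE)
  dA <- sub$dA_cm2[o][seq(1, nrow(sub), by = length(tt))]
  list(t = tt, V = V, dA = dA)
}

.trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Spatial-temporal averaged wall shear stress (SA-WSS)
#'
#' Computes
#' \deqn{\bar\tau_0 = \frac{1}{S T}\int_0^T\!\!\int_{\partial\Omega}
#'       \tau(s,t)\, dA\, dt}
#' for one leaflet side: the area integral as the area-weighted nodal sum
#' (S is the sum of the side's area weights), the time integral by the
#' trapezoid rule on the given grid, with no resampling.
#'
#' @param field A shear [field_series()].
#' @param side Which leaflet side to average (default `"ventricular"`,
#'   whose predominantly unidirectional shear feeds the signaling model).
#' @return SA-WSS in Pa.
#' @export
sa_wss <- function(field, side = "ventricular") {
  stopifnot(inherits(field, "field_series"))
  m <- .side_matrix(field, side)
  S <- sum(m$dA)
  if (S <= 0) stop("zero_area_error: total area weight is zero",
                   call. = FALSE)
  Tcyc <- max(m$t) - min(m$t)
  if (Tcyc <= 0) stop("field_error: degenerate time interval", call. = FALSE)
  spatial <- drop(crossprod(m$dA, m$V)) / S
  .trapz(m$t, spatial) / Tcyc
}

#' Temporally averaged maximum tissue strain
#'
#' Computes
#' \deqn{\bar\epsilon_0 = \frac{1}{T}\int_0^T \max_\Omega
#'       |\epsilon(s,t)|\, dt}
#' with the maximum of the strain magnitude taken over all nodes at each
#' time sample and the time integral by the trapezoid rule. The strain
#' magnitudes are taken as provided (maximum principal strain); no tensors
#' are computed here.
#'
#' @param field A strain [field_series()].
#' @param side Optional side filter; by default the maximum is taken over
#'   the whole tissue domain (all rows).
#' @return Averaged maximum strain (dimensionless).
#' @export
avg_max_strain <- function(field, side = NULL) {
  stopifnot(inherits(field, "field_series"))
  sides <- if (is.null(side)) unique(field$side) else side
  mats <- lapply(sides, function(s) .side_matrix(field, s))
  tt <- mats[[1]]$t
  for (m in mats)
    if (!isTRUE(all.equal(m$t, tt)))
      stop("field_error: sides must share the time grid for a domain-wide ",
           "maximum", call. = FALSE)
  vmax <- do.call(pmax, lapply(mats, function(m) apply(abs(m$V), 2, max)))
  Tcyc <- max(tt) - min(tt)
  if (Tcyc <= 0) stop("field_error: degenerate time interval", call. = FALSE)
  .trapz(tt, vmax) / Tcyc
}

#' Generate synthetic shear and strain fields
#'
#' Emulates the averaged output of a fluid-structure simulation of one
#' cardiac cycle (T = 1 s): a systole-like shear pulse (half-sine squared
#' burst over early systole on a small baseline) and a diastole-peaked
#' strain plateau (leaflets bend most when closed), both with node-level
#' amplitude heterogeneity and uneven area weights. Node amplitudes depend
#' only on `seed` and `n_nodes`, so refining `n_times` refines the
#' quadrature of the same underlying field. Default magnitudes bracket the
#' physiological range (SA-WSS about 1-2.5 Pa, averaged maximum strain
#' about 0.2-0.3).
#'
#' @param n_nodes,n_times Mesh size and samples per cycle (both >= 2).
#' @param seed Integer seed; identical seeds give identical fields.
#' @param tau_amplitude Mean nodal peak shear in Pa (default 7).
#' @param strain_peak Mean nodal plateau strain (default 0.33).
#' @param side Side label for the generated nodes.
#' @return List with elements `shear` and `strain`, both [field_series()].
#' @export
generate_synthetic_fields <- function(n_nodes, n_times, seed = 0,
                                      tau_amplitude = 7,
                                      strain_peak = 0.33,
                                      side = "ventricular") {
  if (n_nodes < 2L || n_times < 2L)
    stop("generator_error: n_nodes and n_times must both be >= 2",
         call. = FALSE)
  u <- withr_seed(seed, function() {
    list(a = stats::runif(n_nodes), w = stats::runif(n_nodes),
         b = stats::runif(n_nodes))
  })
  Tcyc <- 1.0
  tt <- seq(0, Tcyc, length.out = n_times)
  amp <- tau_amplitude * (0.7 + 0.6 * u$a)
  dA <- 12 / n_nodes * (0.8 + 0.4 * u$w)
  bmp <- strain_peak * (0.85 + 0.3 * u$b)

  t_sys <- 0.35
  pulse <- ifelse(tt < t_sys, sin(pi * tt / t_sys)^2, 0) + 0.05
  # diastolic plateau: closed-valve bending from ~0.45 s onward
  plateau <- 0.35 + 0.65 * 0.5 * (1 + tanh((tt - 0.5) / 0.05))

  grid <- expand.grid(node = seq_len(n_nodes), it = seq_len(n_times))
  shear <- field_series(
    node_id = grid$node, time_s = tt[grid$it],
    value = amp[grid$node] * pulse[grid$it],
    dA_cm2 = dA[grid$node], side = side, quantity = "shear")
  strain <- field_series(
    node_id = grid$node, time_s = tt[grid$it],
    value = bmp[grid$node] * plateau[grid$it],
    dA_cm2 = dA[grid$node], side = side, quantity = "strain")
  list(shear = shear, strain = strain)
}

# run fn with a temporary RNG state so generators do not disturb the
# caller's random stream
withr_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Build a mechanical input from a pair of field series
#'
#' Reduces nodal shear and strain series into the per-case averaged inputs
#' ([sa_wss()] and [avg_max_strain()]) of the signaling model.
#'
#' @param shear,strain [field_series()] objects.
#' @param thickness_mm Leaflet thickness label in mm.
#' @param side Side whose SA-WSS feeds the model (default ventricular).
#' @param ... Passed to [mechanical_input()] (`k_td`, `tau_ref`, `name`).
#' @return A [mechanical_input()].
#' @export
mechanical_input_from_fields <- function(shear, strain, thickness_mm,
                                         side = "ventricular", ...) {
  mechanical_input(thickness_mm,
                   tau0 = sa_wss(shear, side = side),
                   eps0 = avg_max_strain(strain), ...)
}
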