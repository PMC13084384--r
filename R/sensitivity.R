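# One-at-a-time local sensitivity analysis: each model quantity is scaled
# up and down by a fixed fraction, the system is re-simulated, and the
# relative change in terminal calcification is recorded.

#' Quantity inventory for the sensitivity scan
#'
#' All 73 scanned quantities: the 12 inflammation rates, the 39
#' SMAD-module rates (including gamma and k_c), the 15 NO-module rates,
#' the coupling parameters xi, a0, a1 and the NO-production fit parameters
#' b0, b1, plus the two mechanical inputs tau0 and eps0. The feedback
#' constants k_td and tau_ref are fixed model structure, not scanned.
#'
#' @param params A `cavd_parameters` object.
#' @return Data frame with columns `quantity` and `class`
#'   (`"rate constant"`, `"coupling parameter"`, `"mechanical input"`).
#' @export
sensitivity_inventory <- function(params) {
  stopifnot(inherits(params, "cavd_parameters"))
  q <- setdiff(names(params$values), c("k_td", "tau_ref"))
  cls <- ifelse(q %in% c("xi", "a0", "a1", "b0", "b1"),
                "coupling parameter", "rate constant")
  rbind(data.frame(quantity = q, class = cls),
        data.frame(quantity = c("tau0", "eps0"),
                   class = "mechanical input"))
}

.perturbed_run <- function(config, params, quantity, factor) {
  if (quantity %in% c("tau0", "eps0")) {
    mech <- config$case
    mech[[quantity]] <- mech[[quantity]] * factor
    config$case <- mechanical_input(mech$thickness_mm, mech$tau0, mech$eps0,
                                    k_td = mech$k_td,
                                    tau_ref = mech$tau_ref,
                                    name = mech$name)
  } else if (quantity %in% names(params$values)) {
    params$values[[quantity]] <- params$values[[quantity]] * factor
  }
  # quantities absent from both the parameter set and the mechanical input
  # leave the model unchanged (dead-parameter rows report zero change)
  traj <- simulate_case(config, params)
  traj$Ca[nrow(traj)]
}

#' One-at-a-time sensitivity scan of terminal calcification
#'
#' For every inventory quantity and both perturbation signs, re-simulates
#' each case with only that quantity scaled and records
#' `|Ca_perturbed - Ca_base| / Ca_base` at the horizon. Parameters are
#' varied by `frac_param` (default 10%), the mechanical inputs by
#' `frac_mech` (default 15%). Perturbed runs that fail to integrate are
#' recorded as failed rows, never dropped.
#'
#' @param params A `cavd_parameters` object.
#' @param cases List of [mechanical_input()] cases (default: all three
#'   reference thicknesses).
#' @param config Optional [run_config()] template (its case is replaced per
#'   scan case); default 23-year horizon.
#' @param frac_param,frac_mech Perturbation fractions.
#' @param quantities Inventory data frame (default
#'   [sensitivity_inventory()]); extra quantities the right-hand side never
#'   reads report exactly zero change, which serves as a dead-parameter
#'   detector.
#' @return A `sensitivity_report` data frame: one row per quantity x case
#'   with `ca_base`, `ca_plus`, `ca_minus`, `rel_plus`, `rel_minus`,
#'   `rel_max` and `failed`.
#' @export
sensitivity_scan <- function(params, cases = case_library(), config = NULL,
                             frac_param = 0.10, frac_mech = 0.15,
                             quantities = sensitivity_inventory(params)) {
  stopifnot(inherits(params, "cavd_parameters"))
  if (is.null(config))
    config <- run_config(case = cases[[1]], horizon_years = 23)
  if (is.null(names(cases)))
    names(cases) <- vapply(cases, `[[`, "", "name")
  base <- vapply(names(cases), function(cn) {
    cfg <- config; cfg$case <- cases[[cn]]
    traj <- simulate_case(cfg, params)
    traj$Ca[nrow(traj)]
  }, 0)
  rows <- vector("list", nrow(quantities) * length(cases))
  ri <- 0L
  for (qi in seq_len(nrow(quantities))) {
    q <- quantities$quantity[qi]
    cls <- quantities$class[qi]
    frac <- if (cls == "mechanical input") frac_mech else frac_param
    for (cn in names(cases)) {
      cfg <- config; cfg$case <- cases[[cn]]
      vals <- vapply(c(1 + frac, 1 - frac), function(fct) {
        tryCatch(.perturbed_run(cfg, params, q, fct),
                 error = function(e) NA_real_)
      }, 0)
      rel <- abs(vals - base[[cn]]) / base[[cn]]
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        quantity = q, class = cls, case = cn, perturbation = frac,
        ca_base = base[[cn]], ca_plus = vals[1], ca_minus = vals[2],
        rel_plus = rel[1], rel_minus = rel[2],
        rel_max = max(rel, na.rm = !all(is.na(rel))),
        failed = any(is.na(vals)))
    }
  }
  report <- do.call(rbind, rows)
  structure(report, class = c("sensitivity_report", "data.frame"),
            frac_param = frac_param, frac_mech = frac_mech,
            horizon_years = config$horizon_years)
}

#' Rank quantities by their maximum relative effect
#'
#' Aggregates a [sensitivity_scan()] report to the maximum relative change
#' per quantity over both signs and all cases, sorts in decreasing order,
#' and counts the quantities exceeding the cutoff.
#'
#' @param report A `sensitivity_report`.
#' @param cutoff Relative-change cutoff (default 0.10).
#' @return Data frame sorted by `rel_max` with attribute `n_above` (also
#'   reported by `print`).
#' @export
sensitivity_rank <- function(report, cutoff = 0.10) {
  stopifnot(inherits(report, "sensitivity_report"))
  agg <- stats::aggregate(rel_max ~ quantity + class, data = report,
                          FUN = max)
  agg <- agg[order(-agg$rel_max, agg$quantity), ]
  rownames(agg) <- NULL
  structure(agg, n_above = sum(agg$rel_max > cutoff), cutoff = cutoff)
}

#' Write a sensitivity report to CSV
#' @param report A `sensitivity_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
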