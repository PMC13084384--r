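# YAML run-configuration schema: a single document with sections
# {case, run, solver, paths}. Mechanical quantities carry explicit unit
# tags; unknown keys warn rather than fail.

.known_config_keys <- list(
  top = c("case", "run", "solver", "paths"),
  case = c("name", "thickness_mm", "tau0", "eps0", "k_td", "tau_ref"),
  run = c("horizon_years", "output_months", "threshold", "side"),
  solver = c("rtol", "atol_scale", "method", "check_tolerance"),
  paths = c("parameters", "out_dir"))

.expected_config_units <- c(tau0 = "Pa", eps0 = "1", k_td = "1/Agatston",
                            tau_ref = "Pa")

#' Validate a run-configuration file
#'
#' Schema check with actionable messages. All violations are enumerated
#' (not first-failure); unknown keys produce warnings, not errors;
#' mechanical quantities must carry the expected unit tag (e.g. `tau0`
#' must be tagged `Pa`, not dyn/cm^2).
#'
#' @param path YAML config path.
#' @return List with `ok` (logical), `errors`, `warnings`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path))
    return(list(ok = FALSE,
                errors = paste0("config file not found: ", path),
                warnings = character(0)))
  doc <- tryCatch(yaml::read_yaml(path), error = function(e) e)
  if (inherits(doc, "error"))
    return(list(ok = FALSE,
                errors = paste0("malformed YAML: ", conditionMessage(doc)),
                warnings = character(0)))
  errors <- character(0); warnings <- character(0)
  unknown <- setdiff(names(doc), .known_config_keys$top)
  if (length(unknown))
    warnings <- c(warnings, paste0("unknown top-level key(s) ignored: ",
                                   paste(unknown, collapse = ", ")))
  for (sec in intersect(names(doc), .known_config_keys$top)) {
    unknown <- setdiff(names(doc[[sec]]), .known_config_keys[[sec]])
    if (length(unknown))
      warnings <- c(warnings, paste0("unknown key(s) in '", sec,
                                     "' ignored: ",
                                     paste(unknown, collapse = ", ")))
  }
  cs <- doc$case
  if (is.null(cs)) {
    errors <- c(errors, "missing 'case' section")
  } else if (is.null(cs$name)) {
    for (f in c("tau0", "eps0")) {
      e <- cs[[f]]
      if (is.null(e)) {
        errors <- c(errors, paste0("case.", f,
                                   " is required when no case name is given"))
      } else if (!is.list(e) || is.null(e$value) || is.null(e$units)) {
        errors <- c(errors, paste0("case.", f,
                                   " must be {value, units}; units must be '",
                                   .expected_config_units[[f]], "'"))
      } else if (!identical(as.character(e$units),
                            .expected_config_units[[f]])) {
        errors <- c(errors, paste0("case.", f, ": units '", e$units,
                                   "' are not the expected '",
                                   .expected_config_units[[f]], "'"))
      }
    }
    if (is.null(cs$thickness_mm))
      errors <- c(errors, "case.thickness_mm is required")
  } else if (!cs$name %in% names(case_library())) {
    errors <- c(errors, paste0("case.name '", cs$name,
                               "' is not one of: ",
                               paste(names(case_library()), collapse = ", ")))
  }
  rn <- doc$run
  if (!is.null(rn)) {
    if (!is.null(rn$horizon_years) &&
        (!is.numeric(rn$horizon_years) || rn$horizon_years <= 0))
      errors <- c(errors, "run.horizon_years must be a positive number")
    if (!is.null(rn$threshold) &&
        (!is.numeric(rn$threshold) || rn$threshold <= 0))
      errors <- c(errors, "run.threshold must be a positive number")
    if (!is.null(rn$side) && !rn$side %in% c("ventricular", "aortic"))
      errors <- c(errors, "run.side must be 'ventricular' or 'aortic'")
  }
  sv <- doc$solver
  if (!is.null(sv)) {
    for (f in c("rtol", "atol_scale"))
      if (!is.null(sv[[f]]) && (!is.numeric(sv[[f]]) || sv[[f]] <= 0))
        errors <- c(errors, paste0("solver.", f,
                                   " must be a positive number"))
  }
  if (!is.null(doc$paths$parameters) &&
      !file.exists(doc$paths$parameters))
    errors <- c(errors, paste0("paths.parameters does not exist: ",
                               doc$paths$parameters))
  list(ok = length(errors) == 0L, errors = errors, warnings = warnings)
}

#' Load a run configuration from YAML
#'
#' Builds a [run_config()] from a validated YAML document. The case is
#' either named (one of the reference thickness cases) or given explicitly
#' with unit-tagged `tau0`/`eps0`.
#'
#' @param path YAML config path.
#' @return A [run_config()].
#' @export
load_run_config <- function(path) {
  rep <- validate_config(path)
  for (w in rep$warnings) warning(w, call. = FALSE)
  if (!rep$ok)
    stop("config_error: invalid configuration:\n  - ",
         paste(rep$errors, collapse = "\n  - "), call. = FALSE)
  doc <- yaml::read_yaml(path)
  cs <- doc$case
  num_or <- function(x, d) if (is.null(x)) d else as.numeric(x)
  if (!is.null(cs$name)) {
    mech <- case_library(k_td = num_or(cs$k_td$value, 0.006),
                         tau_ref = num_or(cs$tau_ref$value, 2))[[cs$name]]
  } else {
    mech <- mechanical_input(cs$thickness_mm,
                             tau0 = cs$tau0$value, eps0 = cs$eps0$value,
                             k_td = num_or(cs$k_td$value, 0.006),
                             tau_ref = num_or(cs$tau_ref$value, 2))
  }
  rn <- doc$run %||% list()
  sv <- doc$solver %||% list()
  run_config(case = mech,
             horizon_years = num_or(rn$horizon_years, 23),
             output_months = num_or(rn$output_months, 1),
             threshold = num_or(rn$threshold, 400),
             rtol = num_or(sv$rtol, 1e-6),
             atol_scale = num_or(sv$atol_scale, 1e-6),
             method = sv$method %||% "lsoda",
             check_tolerance = isTRUE(sv$check_tolerance),
             params_path = doc$paths$parameters,
             side = rn$side %||% "ventricular")
}
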