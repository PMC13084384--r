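#' Per-case mechanical input for the signaling model
#'
#' Bundles the two averaged hemodynamic quantities produced by a
#' fluid-structure simulation of one cardiac cycle -- the spatial-temporal
#' averaged wall shear stress and the temporally averaged maximum tissue
#' strain -- together with the constants of the mechanochemical feedback
#' laws ([wss_update()], [strain_update()]).
#'
#' @param thickness_mm Leaflet thickness in mm (positive; identifies the
#'   case, not used by the equations).
#' @param tau0 Initial SA-WSS in Pa (non-negative).
#' @param eps0 Initial averaged maximum strain, dimensionless in (0, 1).
#' @param k_td Feedback decay constant in Agatston^-1 (non-negative,
#'   default 0.006; zero disables the shear feedback).
#' @param tau_ref Healthy reference shear in Pa (positive, default 2).
#' @param name Optional case label.
#' @return An object of class `mechanical_input`.
#' @export
mechanical_input <- function(thickness_mm, tau0, eps0, k_td = 0.006,
                             tau_ref = 2, name = NULL) {
  stopifnot(is.numeric(thickness_mm), length(thickness_mm) == 1L,
            thickness_mm > 0)
  if (!is.numeric(tau0) || length(tau0) != 1L || !is.finite(tau0) || tau0 < 0)
    stop("mechanical_input: tau0 must be a non-negative finite scalar (Pa)",
         call. = FALSE)
  if (!is.numeric(eps0) || length(eps0) != 1L || !is.finite(eps0) ||
      eps0 <= 0 || eps0 >= 1)
    stop("mechanical_input: eps0 must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(k_td) || k_td < 0)
    stop("mechanical_input: k_td must be non-negative (Agatston^-1); ",
         "zero disables the shear feedback", call. = FALSE)
  if (!is.numeric(tau_ref) || tau_ref <= 0)
    stop("mechanical_input: tau_ref must be positive (Pa)", call. = FALSE)
  structure(
    list(name = name %||% sprintf("h%.2gmm", thickness_mm),
         thickness_mm = thickness_mm, tau0 = tau0, eps0 = eps0,
         k_td = k_td, tau_ref = tau_ref),
    class = "mechanical_input")
}

#' @export
print.mechanical_input <- function(x, ...) {
  cat(sprintf(
    "<mechanical_input '%s'> h = %g mm, tau0 = %g Pa, eps0 = %g, k_td = %g /Agatston, tau_ref = %g Pa\n",
    x$name, x$thickness_mm, x$tau0, x$eps0, x$k_td, x$tau_ref))
  invisible(x)
}

#' Reference leaflet-thickness cases
#'
#' The three leaflet thicknesses studied with the fluid-structure solver,
#' with their averaged shear and strain outputs: a thin physiological
#' leaflet (0.3 mm), an intermediate one (0.5 mm), and a pathologically
#' thickened leaflet (0.75 mm). Thicker leaflets open less, so they see
#' both lower average shear and lower strain.
#'
#' @param k_td,tau_ref Feedback constants shared by all cases (defaults
#'   0.006 Agatston^-1 and 2 Pa).
#' @return Named list of [mechanical_input()] objects: `thin`, `mid`,
#'   `thick`.
#' @export
case_library <- function(k_td = 0.006, tau_ref = 2) {
  list(
    thin  = mechanical_input(0.30, tau0 = 2.23, eps0 = 0.270,
                             k_td = k_td, tau_ref = tau_ref, name = "thin"),
    mid   = mechanical_input(0.50, tau0 = 2.36, eps0 = 0.262,
                             k_td = k_td, tau_ref = tau_ref, name = "mid"),
    thick = mechanical_input(0.75, tau0 = 1.33, eps0 = 0.236,
                             k_td = k_td, tau_ref = tau_ref, name = "thick")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
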