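#' Effective wall shear stress at a given calcification level
#'
#' The spatially and temporally averaged wall shear stress (SA-WSS) is assumed
#' to decay exponentially as calcium burden stiffens the leaflets and impairs
#' opening:
#' \deqn{\bar\tau = \bar\tau_0 \, e^{-k_{td} [Ca]}}
#' where `[Ca]` is the Agatston score and `k_td` (Agatston^-1) sets how fast
#' calcification degrades the shear environment.
#'
#' @param ca Agatston score, a non-negative scalar or vector.
#' @param mech A [mechanical_input()] object supplying `tau0` (Pa) and `k_td`.
#' @return Effective SA-WSS in Pa, same length as `ca`.
#' @seealso [strain_update()] for the companion strain law.
#' @export
wss_update <- function(ca, mech) {
  stopifnot(inherits(mech, "mechanical_input"))
  if (any(!is.finite(ca)) || any(ca < 0)) {
    stop("wss_update: calcification score must be finite and non-negative",
         call. = FALSE)
  }
  mech$tau0 * exp(-mech$k_td * ca)
}

#' Effective averaged maximum strain at a given calcification level
#'
#' As calcification progresses, leaflet deformation is driven toward the
#' typical strain observed in heavily calcified valves (0.2), regardless of
#' the initial strain:
#' \deqn{\bar\epsilon = \frac{0.2\,[Ca] + 1}{[Ca] + 1/\bar\epsilon_0}}
#' At `[Ca] = 0` this returns the initial strain `eps0`; as `[Ca]` grows it
#' approaches 0.2 from above when `eps0 > 0.2` and from below when
#' `eps0 < 0.2`. The cap at 0.2 is enforced only through this asymptote,
#' never by clipping.
#'
#' @param ca Agatston score, non-negative scalar or vector.
#' @param mech A [mechanical_input()] object supplying `eps0`.
#' @return Effective averaged maximum strain (dimensionless).
#' @export
strain_update <- function(ca, mech) {
  stopifnot(inherits(mech, "mechanical_input"))
  if (mech$eps0 <= 0) {
    stop("strain_update: initial strain eps0 must be positive", call. = FALSE)
  }
  if (any(!is.finite(ca)) || any(ca < 0)) {
    stop("strain_update: calcification score must be finite and non-negative",
         call. = FALSE)
  }
  (0.2 * ca + 1) / (ca + 1 / mech$eps0)
}

#' Shear-modulated transport rate
#'
#' High shear reinforces endothelial junctions and reduces both
#' transendothelial LDL transport and monocyte adhesion, so the base rates
#' for LDL penetration (`k_inf1`) and monocyte capture (`k_inf5`) are damped
#' by the factor \eqn{1/(1 + \bar\tau/\bar\tau_{ref})}. At zero shear the
#' base rate is returned unchanged; at the healthy reference shear it is
#' halved.
#'
#' @param k_bar Shear-free base rate (any rate unit).
#' @param tau Effective SA-WSS in Pa (non-negative).
#' @param tau_ref Reference SA-WSS in Pa (positive; 2 Pa represents the
#'   healthy valve).
#' @return The modulated rate, same units as `k_bar`.
#' @export
shear_modulated_rate <- function(k_bar, tau, tau_ref) {
  stopifnot(all(k_bar >= 0), all(tau >= 0), tau_ref > 0)
  k_bar / (1 + tau / tau_ref)
}

#' Strain magnification factor
#'
#' Tissue strain promotes interstitial-cell crowding, paracrine TGF-beta
#' signaling, and apoptotic nucleation of calcific nodules. These effects
#' are lumped into an exponential magnification term
#' \deqn{h_e = a_0 (e^{a_1 \bar\epsilon} - 1)}
#' which is zero in the absence of strain and grows convexly with it.
#'
#' @param eps Effective averaged maximum strain (non-negative).
#' @param a0,a1 Dimensionless magnification coefficients
#'   (defaults 4.435e4 and 6.404).
#' @return The dimensionless magnification factor `h_e`.
#' @export
strain_magnification <- function(eps, a0 = 4.435e4, a1 = 6.404) {
  stopifnot(all(eps >= 0), a0 > 0, a1 > 0)
  a0 * (exp(a1 * eps) - 1)
}

#' Strain-dependent calcification rate constants
#'
#' The rate constants for calcium production by nuclear pSMAD3 (`k_sma26`)
#' and pSMAD2 (`k_sma27`) scale with the strain magnification factor:
#' \deqn{k_{sma26} = \gamma k_c (1 + h_e), \qquad
#'       k_{sma27} = \gamma \xi k_c (1 + h_e)}
#' `gamma` converts calcific-nodule counts (nodules/well) to Agatston score,
#' `k_c` is the baseline calcification rate in nodules/well/(M s), and
#' `xi` in [0, 1] is the relative contribution of SMAD2- versus
#' SMAD3-mediated calcification (SMAD3 dominates, so `xi < 1` scales the
#' SMAD2 branch).
#'
#' @param h_e Strain magnification factor from [strain_magnification()].
#' @param gamma Nodules/well to Agatston conversion factor (non-negative).
#' @param k_c Baseline calcification rate constant (non-negative).
#' @param xi SMAD2:SMAD3 calcification ratio in [0, 1].
#' @return Named numeric vector with elements `k_sma26` and `k_sma27`,
#'   in Agatston/(M s).
#' @export
calcification_rate_constants <- function(h_e, gamma, k_c, xi) {
  stopifnot(all(h_e >= 0), gamma >= 0, k_c >= 0, xi >= 0, xi <= 1)
  k26 <- gamma * k_c * (1 + h_e)
  c(k_sma26 = k26, k_sma27 = xi * k26)
}

#' Shear-dependent NO production rate
#'
#' Endothelial NO synthesis increases with wall shear stress and saturates
#' at high shear. The implemented form is a rectangular hyperbola fitted to
#' flow-chamber NO production data:
#' \deqn{k_{NO}(\bar\tau) = b_0 \frac{\bar\tau}{b_1 + \bar\tau}}
#' so that `k_NO(0) = 0` (no flow, no flow-induced production) and
#' `k_NO -> b0` as shear grows.
#'
#' @param tau Effective SA-WSS in Pa (non-negative).
#' @param b0 Saturation production rate in M/s (non-negative).
#' @param b1 Half-saturation shear in Pa (positive).
#' @return Flow-induced NO production rate in M/s.
#' @export
no_production_rate <- function(tau, b0, b1) {
  stopifnot(all(tau >= 0), b0 >= 0, b1 > 0)
  b0 * tau / (b1 + tau)
}
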