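#' Valvular tissue properties used for unit conversion
#'
#' The inflammation submodel is formulated in the source literature on a
#' cellular-concentration basis (items per cm^2 of leaflet tissue), whereas
#' the SMAD and NO submodels use volume-molar concentrations. These tissue
#' properties define the bridge between the two bases.
#'
#' @param S Total leaflet surface area, cm^2 (default 12).
#' @param S_vic Total area occupied by valvular interstitial cells, cm^2
#'   (default 6; must not exceed `S`).
#' @param V_vec Volume of one valvular endothelial cell, litres
#'   (default 2e-12).
#' @param rho_vec Endothelial cell surface density, cells/cm^2
#'   (default 1e4).
#' @param rho_vic Interstitial cell tissue density, cells/cm^2
#'   (default 5e4).
#' @param alpha Foam-cell formation ratio, cells/g (default 5.7e-6): the
#'   ratio of the LDL-oxidation and foam-cell-formation rates, used to
#'   rescale the oxLDL-to-foam-cell branch.
#' @return An object of class `tissue_properties`.
#' @export
tissue_properties <- function(S = 12, S_vic = 6, V_vec = 2e-12,
                              rho_vec = 1e4, rho_vic = 5e4,
                              alpha = 5.7e-6) {
  vals <- c(S = S, S_vic = S_vic, V_vec = V_vec, rho_vec = rho_vec,
            rho_vic = rho_vic, alpha = alpha)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("tissue_properties: all properties must be positive and finite",
         call. = FALSE)
  if (S_vic > S)
    stop("tissue_properties: S_vic cannot exceed the total leaflet area S",
         call. = FALSE)
  structure(as.list(vals), class = "tissue_properties")
}

#' @export
print.tissue_properties <- function(x, ...) {
  cat("<tissue_properties>\n")
  cat(sprintf("  S = %g cm^2, S_vic = %g cm^2, V_vec = %g L\n",
              x$S, x$S_vic, x$V_vec))
  cat(sprintf("  rho_vec = %g cells/cm^2, rho_vic = %g cells/cm^2, alpha = %g cells/g\n",
              x$rho_vec, x$rho_vic, x$alpha))
  invisible(x)
}

# Liquid volume per unit tissue area (L/cm^2): endothelial cell volume times
# surface density. Multiplying by Avogadro's number gives the factor that
# converts an areal item density (items/cm^2) into a molar concentration.
.area_to_molar_factor <- function(tissue) {
  n_avogadro <- 6.02214076e23
  n_avogadro * tissue$rho_vec * tissue$V_vec
}

#' Convert an inflammation-pathway rate constant between concentration bases
#'
#' Rescales a rate constant from the cellular (areal) basis of the
#' inflammation literature to the volume-molar basis shared by the SMAD and
#' NO submodels, using the leaflet tissue properties. The scaling depends on
#' the reaction order:
#' \describe{
#'   \item{`"zeroth"`}{items/cm^2/s -> M/s: divide by
#'     `N_A * rho_vec * V_vec` (the areal-to-molar factor), and scale by
#'     the interstitial-to-total area ratio `S_vic/S` for sources acting on
#'     the interstitial compartment.}
#'   \item{`"first"`}{1/s -> 1/s: unchanged; first-order constants are
#'     basis-independent.}
#'   \item{`"second"`}{cm^2/items/s -> 1/(M s): multiply by the
#'     areal-to-molar factor.}
#'   \item{`"foam"`}{the oxLDL -> foam-cell branch: second-order scaling
#'     additionally multiplied by the foam-cell formation ratio `alpha`,
#'     which relates the LDL-oxidation and foam-cell-formation rates.}
#' }
#'
#' @param rate Non-negative rate constant in the cellular basis (or molar
#'   basis when `invert = TRUE`).
#' @param tissue A [tissue_properties()] object.
#' @param kind One of `"zeroth"`, `"first"`, `"second"`, `"foam"`.
#' @param invert If `TRUE`, apply the inverse conversion (molar basis back
#'   to cellular basis).
#' @return The converted rate constant.
#' @export
convert_inflammation_units <- function(rate, tissue,
                                       kind = c("zeroth", "first",
                                                "second", "foam"),
                                       invert = FALSE) {
  if (!inherits(tissue, "tissue_properties"))
    stop("convert_inflammation_units: 'tissue' must be a tissue_properties object",
         call. = FALSE)
  if (!is.character(kind) || !all(kind %in% c("zeroth", "first", "second", "foam")))
    stop("convert_inflammation_units: unknown reaction-order kind '",
         paste(setdiff(kind, c("zeroth", "first", "second", "foam")),
               collapse = "', '"), "'", call. = FALSE)
  kind <- match.arg(kind)
  if (any(!is.finite(rate)) || any(rate < 0))
    stop("convert_inflammation_units: rate must be finite and non-negative",
         call. = FALSE)
  f <- .area_to_molar_factor(tissue)
  factor <- switch(kind,
    zeroth = (tissue$S_vic / tissue$S) / f,
    first  = 1,
    second = f,
    foam   = f * tissue$alpha)
  if (invert) rate / factor else rate * factor
}
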