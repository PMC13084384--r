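# Rule-based construction of the coupled reaction network.
#
# Each biochemical process is declared once as a mass-action rule: a rate
# constant, the species whose concentrations enter the rate monomial (at
# most two; catalysts/modifiers appear here without being consumed), and a
# stoichiometry map. The ODE system is generated from these rules, so every
# right-hand-side term is traceable to a named reaction and the
# stoichiometry matrix is built, not hand-coded.

#' Species of the coupled calcification model
#'
#' Concentrations are volume-molar (M) except `Ca`, the calcification burden
#' in Agatston score.
#'
#' @return Character vector of species names in state-vector order.
#' @export
species_names <- function() {
  c(
    # inflammation (subendothelial compartment)
    "LDL", "oxLDL", "mono", "macro", "foam", "TGFb_lat", "TGFb_act",
    # endothelial NO / cGMP / PKG
    "NO", "sGC", "NOsGC", "cGMP", "PKG", "PKGa",
    # TGF-beta receptor and SMAD2/3 shuttling (c = cytoplasmic, n = nuclear)
    "R", "RC", "S2c", "S3c", "pS2c", "pS3c",
    "S2n", "S3n", "pS2n", "pS3n", "pS3i",
    # clinical calcification score
    "Ca"
  )
}

.rxn <- function(name, module, k, rate_species, stoich) {
  list(name = name, module = module, k = k,
       rate_species = rate_species, stoich = stoich)
}

# The full reaction inventory. Dynamic rate constants (k_inf1, k_inf5, k_NO,
# k_sma26, k_sma27) are recomputed from the instantaneous mechanical state
# inside the RHS; every other constant is read once from the parameter set.
.reaction_list <- function() {
  list(
    ## --- inflammation -----------------------------------------------------
    .rxn("LDL_influx",        "inflammation", "k_inf1",  character(0),
         c(LDL = 1)),
    .rxn("LDL_outdiffusion",  "inflammation", "k_inf2",  "LDL",
         c(LDL = -1)),
    .rxn("LDL_oxidation",     "inflammation", "k_inf3",  "LDL",
         c(LDL = -1, oxLDL = 1)),
    .rxn("foam_formation",    "inflammation", "k_inf4",  c("macro", "oxLDL"),
         c(macro = -1, oxLDL = -1, foam = 1)),
    .rxn("monocyte_capture",  "inflammation", "k_inf5",  "oxLDL",
         c(mono = 1)),
    .rxn("mono_differentiation", "inflammation", "k_inf6", "mono",
         c(mono = -1, macro = 1)),
    .rxn("mono_apoptosis",    "inflammation", "k_inf7",  "mono",
         c(mono = -1)),
    .rxn("macro_apoptosis",   "inflammation", "k_inf8",  "macro",
         c(macro = -1)),
    .rxn("foam_apoptosis",    "inflammation", "k_inf9",  "foam",
         c(foam = -1)),
    .rxn("TGFb_production_macro", "inflammation", "k_inf10", "macro",
         c(TGFb_lat = 1)),
    .rxn("TGFb_production_foam",  "inflammation", "k_inf10", "foam",
         c(TGFb_lat = 1)),
    .rxn("TGFb_activation_macro", "inflammation", "k_inf11",
         c("TGFb_lat", "macro"), c(TGFb_lat = -1, TGFb_act = 1)),
    .rxn("TGFb_activation_foam",  "inflammation", "k_inf11",
         c("TGFb_lat", "foam"), c(TGFb_lat = -1, TGFb_act = 1)),
    .rxn("TGFb_act_degradation",  "inflammation", "k_inf12", "TGFb_act",
         c(TGFb_act = -1)),

    ## --- NO / cGMP / PKG --------------------------------------------------
    .rxn("NO_production",   "no_pkg", "k_NO",     character(0),
         c(NO = 1)),
    .rxn("NO_sGC_binding",  "no_pkg", "k_inh1a",  c("NO", "sGC"),
         c(NO = -1, sGC = -1, NOsGC = 1)),
    .rxn("NO_sGC_unbinding", "no_pkg", "k_inh1b", "NOsGC",
         c(NO = 1, sGC = 1, NOsGC = -1)),
    .rxn("NO_degradation",  "no_pkg", "k_inh2",   "NO",
         c(NO = -1)),
    .rxn("sGC_synthesis",   "no_pkg", "k_inh3",   character(0),
         c(sGC = 1)),
    .rxn("sGC_degradation", "no_pkg", "k_inh4",   "sGC",
         c(sGC = -1)),
    .rxn("NOsGC_recovery",  "no_pkg", "k_inh5",   "NOsGC",
         c(NOsGC = -1, sGC = 1)),
    .rxn("cGMP_production", "no_pkg", "k_inh6",   "NOsGC",
         c(cGMP = 1)),
    .rxn("cGMP_basal_production", "no_pkg", "k_inh7", "sGC",
         c(cGMP = 1)),
    .rxn("cGMP_degradation", "no_pkg", "k_inh8",  "cGMP",
         c(cGMP = -1)),
    .rxn("PKG_activation",  "no_pkg", "k_inh9",   c("cGMP", "PKG"),
         c(PKG = -1, PKGa = 1)),
    .rxn("PKG_deactivation", "no_pkg", "k_inh10", "PKGa",
         c(PKG = 1, PKGa = -1)),
    .rxn("PKG_synthesis",   "no_pkg", "k_inh11",  character(0),
         c(PKG = 1)),
    .rxn("PKG_degradation", "no_pkg", "k_inh12",  "PKG",
         c(PKG = -1)),
    .rxn("PKGa_degradation", "no_pkg", "k_inh13", "PKGa",
         c(PKGa = -1)),
    .rxn("NOsGC_degradation", "no_pkg", "k_inh14", "NOsGC",
         c(NOsGC = -1)),

    ## --- TGF-beta receptor / SMAD2/3 --------------------------------------
    .rxn("R_synthesis",     "smad", "k_sma1",  character(0), c(R = 1)),
    .rxn("R_degradation",   "smad", "k_sma2",  "R",          c(R = -1)),
    .rxn("RC_binding",      "smad", "k_sma3",  c("TGFb_act", "R"),
         c(TGFb_act = -1, R = -1, RC = 1)),
    .rxn("RC_dissociation", "smad", "k_sma4",  "RC",
         c(TGFb_act = 1, R = 1, RC = -1)),
    .rxn("RC_degradation",  "smad", "k_sma5",  "RC", c(RC = -1)),
    .rxn("RC_recycling",    "smad", "k_sma6",  "RC", c(RC = -1, R = 1)),
    .rxn("S2_synthesis",    "smad", "k_sma7",  character(0), c(S2c = 1)),
    .rxn("S3_synthesis",    "smad", "k_sma8",  character(0), c(S3c = 1)),
    .rxn("S2c_degradation", "smad", "k_sma9",  "S2c", c(S2c = -1)),
    .rxn("S3c_degradation", "smad", "k_sma10", "S3c", c(S3c = -1)),
    .rxn("S2_phosphorylation", "smad", "k_sma11", c("RC", "S2c"),
         c(S2c = -1, pS2c = 1)),
    .rxn("S3_phosphorylation", "smad", "k_sma12", c("RC", "S3c"),
         c(S3c = -1, pS3c = 1)),
    .rxn("S2_basal_phosphorylation", "smad", "k_sma13", "S2c",
         c(S2c = -1, pS2c = 1)),
    .rxn("S3_basal_phosphorylation", "smad", "k_sma14", "S3c",
         c(S3c = -1, pS3c = 1)),
    .rxn("pS2c_dephosphorylation", "smad", "k_sma15", "pS2c",
         c(pS2c = -1, S2c = 1)),
    .rxn("pS3c_dephosphorylation", "smad", "k_sma16", "pS3c",
         c(pS3c = -1, S3c = 1)),
    .rxn("pS2c_import", "smad", "k_sma17", "pS2c", c(pS2c = -1, pS2n = 1)),
    .rxn("pS3c_import", "smad", "k_sma18", "pS3c", c(pS3c = -1, pS3n = 1)),
    .rxn("pS2n_export", "smad", "k_sma19", "pS2n", c(pS2n = -1, pS2c = 1)),
    .rxn("pS3n_export", "smad", "k_sma20", "pS3n", c(pS3n = -1, pS3c = 1)),
    .rxn("S2c_import",  "smad", "k_sma21", "S2c",  c(S2c = -1, S2n = 1)),
    .rxn("S3c_import",  "smad", "k_sma22", "S3c",  c(S3c = -1, S3n = 1)),
    .rxn("S2n_export",  "smad", "k_sma23", "S2n",  c(S2n = -1, S2c = 1)),
    .rxn("S3n_export",  "smad", "k_sma24", "S3n",  c(S3n = -1, S3c = 1)),
    .rxn("pS2n_dephosphorylation", "smad", "k_sma25", "pS2n",
         c(pS2n = -1, S2n = 1)),
    .rxn("pS2n_degradation", "smad", "k_sma28", "pS2n", c(pS2n = -1)),
    .rxn("pS3n_degradation", "smad", "k_sma29", "pS3n", c(pS3n = -1)),
    .rxn("pS3c_inhibition", "smad", "k_sma30", c("PKGa", "pS3c"),
         c(pS3c = -1, pS3i = 1)),
    .rxn("pS3n_inhibition", "smad", "k_sma31", c("PKGa", "pS3n"),
         c(pS3n = -1, pS3i = 1)),
    .rxn("pS3i_degradation", "smad", "k_sma32", "pS3i", c(pS3i = -1)),
    .rxn("pS3i_reversal",    "smad", "k_sma33", "pS3i",
         c(pS3i = -1, pS3c = 1)),
    .rxn("S2n_degradation",  "smad", "k_sma34", "S2n",  c(S2n = -1)),
    .rxn("S3n_degradation",  "smad", "k_sma35", "S3n",  c(S3n = -1)),
    .rxn("pS2c_degradation", "smad", "k_sma36", "pS2c", c(pS2c = -1)),
    .rxn("pS3c_degradation", "smad", "k_sma37", "pS3c", c(pS3c = -1)),
    .rxn("pS3n_dephosphorylation", "smad", "k_sma38", "pS3n",
         c(pS3n = -1, S3n = 1)),
    .rxn("R_upregulation", "smad", "k_sma39", "TGFb_act", c(R = 1)),

    ## --- calcification (production-only; SMAD3 branch dominates) ----------
    .rxn("Ca_production_SMAD3", "smad", "k_sma26", "pS3n", c(Ca = 1)),
    .rxn("Ca_production_SMAD2", "smad", "k_sma27", "pS2n", c(Ca = 1))
  )
}

# Rate-constant names that are recomputed from the mechanical state rather
# than read from the parameter file.
.dynamic_k <- c("k_inf1", "k_inf5", "k_NO", "k_sma26", "k_sma27")

#' Assemble the generated ODE system
#'
#' Compiles the declared reaction rules into the numeric structures used by
#' the right-hand side: the stoichiometry matrix and, for each reaction, the
#' (at most two) state indices entering its mass-action monomial.
#'
#' @return An object of class `ode_system` with elements `species`,
#'   `reactions`, `Smat` (species x reactions stoichiometry), `i1`/`i2`
#'   (1-offset monomial indices into `c(1, state)`), `k_names`, `module`,
#'   and `n_equations` (number of generated species ODEs).
#' @export
ode_system <- function() {
  sp <- species_names()
  rx <- .reaction_list()
  nr <- length(rx)
  Smat <- matrix(0, nrow = length(sp), ncol = nr,
                 dimnames = list(sp, vapply(rx, `[[`, "", "name")))
  i1 <- integer(nr); i2 <- integer(nr)
  for (j in seq_len(nr)) {
    r <- rx[[j]]
    stopifnot(all(names(r$stoich) %in% sp),
              all(r$rate_species %in% sp),
              length(r$rate_species) <= 2L)
    Smat[names(r$stoich), j] <- r$stoich
    idx <- match(r$rate_species, sp)
    i1[j] <- if (length(idx) >= 1L) idx[1L] else 0L
    i2[j] <- if (length(idx) >= 2L) idx[2L] else 0L
  }
  structure(
    list(species = sp, reactions = rx, Smat = Smat,
         i1 = i1 + 1L, i2 = i2 + 1L,
         k_names = vapply(rx, `[[`, "", "k"),
         module = vapply(rx, `[[`, "", "module"),
         n_equations = length(sp)),
    class = "ode_system")
}

#' @export
print.ode_system <- function(x, ...) {
  cat(sprintf("<ode_system> %d species ODEs generated from %d reaction rules\n",
              x$n_equations, length(x$reactions)))
  cat("modules:", paste(sprintf("%s (%d)", names(table(x$module)),
                                table(x$module)), collapse = ", "), "\n")
  invisible(x)
}

# Resolve the full rate-constant vector (one entry per reaction) for a given
# mechanical state. Static entries come from the parameter set; the five
# dynamic entries are evaluated through the coupling laws.
.resolve_rate_constants <- function(sys, params, tau, eps, tau_ref) {
  v <- params$values
  k <- ifelse(sys$k_names %in% .dynamic_k, 0, v[sys$k_names])
  k[sys$k_names == "k_inf1"] <- shear_modulated_rate(v[["kbar_inf1"]], tau, tau_ref)
  k[sys$k_names == "k_inf5"] <- shear_modulated_rate(v[["kbar_inf5"]], tau, tau_ref)
  k[sys$k_names == "k_NO"] <- no_production_rate(tau, v[["b0"]], v[["b1"]])
  h_e <- strain_magnification(eps, v[["a0"]], v[["a1"]])
  kc <- calcification_rate_constants(h_e, v[["gamma"]], v[["k_c"]], v[["xi"]])
  k[sys$k_names == "k_sma26"] <- kc[["k_sma26"]]
  k[sys$k_names == "k_sma27"] <- kc[["k_sma27"]]
  unname(k)
}

.check_state <- function(state, sys) {
  if (length(state) != length(sys$species))
    stop("state vector must have ", length(sys$species), " entries",
         call. = FALSE)
  if (is.null(names(state))) names(state) <- sys$species
  if (any(!is.finite(state)))
    stop("state vector contains non-finite entries", call. = FALSE)
  scale <- pmax(abs(state), 1e-12)
  if (any(state < -1e-6 * scale - 1e-15))
    stop("negative species concentrations beyond tolerance", call. = FALSE)
  state
}

.reaction_rates <- function(sys, state, k) {
  s <- c(1, pmax(state, 0))
  k * s[sys$i1] * s[sys$i2]
}

.partial_rhs <- function(sys, state, k, modules) {
  r <- .reaction_rates(sys, state, k)
  keep <- sys$module %in% modules
  out <- drop(sys$Smat[, keep, drop = FALSE] %*% r[keep])
  names(out) <- sys$species
  out
}

.sys_cache <- new.env(parent = emptyenv())
.get_sys <- function() {
  if (is.null(.sys_cache$sys)) .sys_cache$sys <- ode_system()
  .sys_cache$sys
}

#' Inflammation-pathway right-hand side
#'
#' Time derivatives contributed by the LDL/monocyte/macrophage/foam-cell/
#' TGF-beta reactions at a given state and effective shear. Shear enters
#' only through the LDL-penetration and monocyte-capture rates
#' ([shear_modulated_rate()]).
#'
#' @param state Named state vector over [species_names()] (volume-molar; `Ca`
#'   in Agatston).
#' @param params A [load_parameters()] parameter set.
#' @param tau Effective SA-WSS in Pa.
#' @param tau_ref Reference shear in Pa (default 2).
#' @return Named vector of time derivatives (M/s; Agatston/s for `Ca`);
#'   entries outside the module are zero.
#' @export
rhs_inflammation <- function(state, params, tau, tau_ref = 2) {
  sys <- .get_sys()
  state <- .check_state(state, sys)
  k <- .resolve_rate_constants(sys, params, tau, eps = 0, tau_ref = tau_ref)
  .partial_rhs(sys, state, k, "inflammation")
}

#' NO/cGMP/PKG-pathway right-hand side
#'
#' Derivatives from the endothelial NO module. The NO balance is
#' `d[NO]/dt = k_NO(tau) + k_inh1b[NO-sGC] - k_inh2[NO] - k_inh1a[NO][sGC]`,
#' with downstream cGMP production by the NO-sGC complex and cGMP-dependent
#' PKG activation.
#'
#' @inheritParams rhs_inflammation
#' @return Named derivative vector; entries outside the module are zero.
#' @export
rhs_no_pkg <- function(state, params, tau, tau_ref = 2) {
  sys <- .get_sys()
  state <- .check_state(state, sys)
  k <- .resolve_rate_constants(sys, params, tau, eps = 0, tau_ref = tau_ref)
  .partial_rhs(sys, state, k, "no_pkg")
}

#' SMAD-pathway and calcification right-hand side
#'
#' Derivatives from TGF-beta receptor binding, SMAD2/3 phosphorylation and
#' nucleocytoplasmic shuttling, PKG-dependent pSMAD3 inhibition, and the
#' production-only calcification terms whose rate constants scale with the
#' strain magnification factor ([calcification_rate_constants()]).
#'
#' @inheritParams rhs_inflammation
#' @param eps Effective averaged maximum strain (dimensionless).
#' @return Named derivative vector; entries outside the module are zero.
#' @export
rhs_smad <- function(state, params, eps) {
  sys <- .get_sys()
  state <- .check_state(state, sys)
  k <- .resolve_rate_constants(sys, params, tau = 0, eps = eps, tau_ref = 2)
  .partial_rhs(sys, state, k, "smad")
}

#' Full coupled right-hand side
#'
#' Evaluates the quasi-steady mechanical state from the instantaneous
#' calcification score -- `tau = wss_update(Ca)`, `eps = strain_update(Ca)`
#' -- and sums the three pathway contributions. The mechanics influence the
#' network only through the five coupled rate constants (k_inf1, k_inf5,
#' k_NO, k_sma26, k_sma27).
#'
#' @param state Named state vector over [species_names()].
#' @param params A [load_parameters()] parameter set.
#' @param mech A [mechanical_input()] case.
#' @return Named vector of time derivatives, with attributes `tau_bar` and
#'   `eps_bar` giving the effective mechanical state used.
#' @export
assemble_rhs <- function(state, params, mech) {
  sys <- .get_sys()
  state <- .check_state(state, sys)
  ca <- max(state[["Ca"]], 0)
  tau <- wss_update(ca, mech)
  eps <- strain_update(ca, mech)
  k <- .resolve_rate_constants(sys, params, tau, eps, mech$tau_ref)
  out <- .partial_rhs(sys, state, k, c("inflammation", "no_pkg", "smad"))
  attr(out, "tau_bar") <- tau
  attr(out, "eps_bar") <- eps
  out
}

#' Dump the generated ODE system in human-readable form
#'
#' Writes one line per species equation, each term annotated with its
#' reaction rule, for audit of the generated system.
#'
#' @param sys An [ode_system()] (default: the packaged system).
#' @param file Optional path; if `NULL` the lines are returned invisibly
#'   and printed.
#' @return Character vector of equation lines, invisibly.
#' @export
dump_odes <- function(sys = ode_system(), file = NULL) {
  term <- function(j) {
    mono <- sys$reactions[[j]]$rate_species
    kname <- sys$k_names[j]
    if (kname %in% .dynamic_k) kname <- paste0(kname, "(t)")
    paste(c(kname, sprintf("[%s]", mono)), collapse = "*")
  }
  lines <- character(0)
  for (i in seq_along(sys$species)) {
    sto <- sys$Smat[i, ]
    jj <- which(sto != 0)
    if (length(jj) == 0L) next
    terms <- vapply(jj, function(j) {
      coef <- sto[j]
      sgn <- if (coef > 0) "+" else "-"
      mult <- if (abs(coef) != 1) paste0(abs(coef), "*") else ""
      sprintf("%s %s%s", sgn, mult, term(j))
    }, "")
    lines <- c(lines, sprintf("d[%s]/dt = %s", sys$species[i],
                              paste(terms, collapse = " ")))
  }
  lines <- c(sprintf("# generated ODE system: %d species equations from %d reaction rules",
                     length(lines), length(sys$reactions)), lines)
  if (!is.null(file)) writeLines(lines, file) else cat(lines, sep = "\n")
  invisible(lines)
}
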