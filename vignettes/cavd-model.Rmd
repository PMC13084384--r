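---
title: "A mechanochemical model of aortic valve calcification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanochemical model of aortic valve calcification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Calcific aortic valve disease (CAVD) progresses over decades through a
feedback between hemodynamics and cell signaling: leaflet stiffening and
calcific nodules impair valve opening, which lowers wall shear stress (WSS)
on the leaflet surfaces and reduces tissue strain; lower shear weakens the
protective endothelial NO/cGMP/PKG axis and raises endothelial permeability
to LDL and monocytes; the resulting inflammation activates TGF-β, drives
SMAD2/3 phosphorylation in valvular interstitial cells, and accelerates
calcium deposition — which further degrades the mechanics. `cavdsim`
implements the biochemical half of this loop: a three-pathway reaction
network driven by two averaged mechanical inputs, with phenomenological
feedback laws that evolve the effective mechanics as the Agatston score
grows.

The mechanical inputs are produced upstream by a fluid–structure
interaction (FSI) simulation of one cardiac cycle and enter as two scalars
per case:

* $\bar\tau_0$ — the spatial–temporal averaged WSS (Pa) over one leaflet
  side and one cycle (`sa_wss()`),
* $\bar\epsilon_0$ — the temporally averaged maximum tissue strain
  (`avg_max_strain()`).

The package ships the three reference cases (`case_library()`): leaflet
thicknesses 0.3, 0.5 and 0.75 mm with
$\bar\tau_0 = 2.23, 2.36, 1.33$ Pa and
$\bar\epsilon_0 = 0.270, 0.262, 0.236$. One FSI cycle per case is assumed
representative of the slowly evolving disease state (a quasi-steady,
one-way coupling); re-running the flow solver as calcification proceeds is
out of scope.

## Mechanochemical coupling laws

With $[Ca]$ the Agatston score, the effective mechanics are algebraic
functions of the instantaneous state, evaluated continuously inside the ODE
right-hand side (no discrete re-coupling events):

$$\bar\tau = \bar\tau_0\, e^{-k_{td} [Ca]}, \qquad
  \bar\epsilon = \frac{0.2\,[Ca] + 1}{[Ca] + 1/\bar\epsilon_0},$$

with $k_{td} = 0.006$ Agatston$^{-1}$. The strain law interpolates from
$\bar\epsilon_0$ at $[Ca]=0$ to the typical calcified-valve strain 0.2 as
$[Ca]\to\infty$; the cap is enforced only through this asymptote, never by
clipping. Note the interpolation scale: the half-way point sits near
$[Ca] \approx 1/\bar\epsilon_0 \approx 4$, so strain differences between
cases act only very early in a multi-decade run, whereas the shear decay
acts on the scale $1/k_{td} \approx 170$ Agatston and shapes the whole
trajectory.

The mechanics touch the network in exactly five rate constants:

* LDL penetration and monocyte capture are damped by shear,
  $k = \bar k / (1 + \bar\tau/\bar\tau_{ref})$ with
  $\bar\tau_{ref} = 2$ Pa (healthy reference);
* flow-induced NO production follows a saturating fit
  $k_{NO}(\bar\tau) = b_0 \bar\tau/(b_1 + \bar\tau)$;
* the two calcium-production constants scale with the strain magnification
  factor $h_e = a_0(e^{a_1 \bar\epsilon} - 1)$
  ($a_0 = 4.435\times 10^4$, $a_1 = 6.404$):
  $k_{sma26} = \gamma k_c (1 + h_e)$ for the SMAD3 branch and
  $k_{sma27} = \gamma \xi k_c (1 + h_e)$ for the SMAD2 branch, with
  $\xi = 0.15$ because SMAD3 is the dominant pro-calcific transducer.

A directionality test asserts that no other term reads the mechanical
state.

## The reaction network

The network is declared as mass-action rules (`ode_system()`); the 25
species ODEs are generated from 69 mass-action rules and can be audited with
`dump_odes()`. Three modules:

**Inflammation** (12 rate constants): zeroth-order subendothelial LDL
penetration, LDL out-diffusion and oxidation; oxLDL-proportional monocyte
capture; monocyte→macrophage differentiation and apoptosis; foam-cell
formation by macrophage uptake of oxLDL; latent TGF-β production by
macrophages and foam cells and its cell-contact-driven activation; active
TGF-β turnover. The displayed LDL and monocyte balances are
term-for-term:
$\dot{[LDL]} = k_{inf1}(\bar\tau) - (k_{inf2}+k_{inf3})[LDL]$ and
$\dot{[mono]} = k_{inf5}(\bar\tau)[oxLDL] - (k_{inf6}+k_{inf7})[mono]$.

**NO/cGMP/PKG** (15 rate constants): flow-induced NO production, NO
degradation, reversible NO–sGC binding with complex turnover, cGMP
production by the NO–sGC complex (plus a small basal term), cGMP
hydrolysis, cGMP-dependent PKG activation and deactivation, and synthesis/
turnover of sGC and PKG. The NO balance is
$\dot{[NO]} = k_{NO}(\bar\tau) + k_{inh1b}[NO\!-\!sGC] - k_{inh2}[NO]
- k_{inh1a}[NO][sGC]$; the degradation and binding constants are kept as
distinct parameters.

**TGF-β receptor / SMAD2/3** (39 quantities including $\gamma$ and
$k_c$): receptor synthesis, turnover and ligand-induced complex formation;
receptor-complex-catalyzed SMAD2/3 phosphorylation (plus ligand-independent
basal terms that default to zero); cytoplasmic↔nuclear shuttling of all
four SMAD forms; dephosphorylation; PKG-dependent conversion of pSMAD3
(cytoplasmic and nuclear) into an inhibited form; and the production-only
calcification terms
$\dot{[Ca]} = k_{sma26}[pSMAD3_n] + k_{sma27}[pSMAD2_n]$, in Agatston per
second. Because calcium terms are production-only, $[Ca]$ is monotone
non-decreasing — asserted on every trajectory.

Two indices (26, 27) are reserved for the derived calcification constants,
so the stored SMAD constants are `k_sma1..k_sma25` and `k_sma28..k_sma39`
plus `gamma` and `k_c`.

## Parameterization and the calibration anchor

All rates live in a single volume-molar (M, s) basis. The inflammation
literature uses a cellular (areal) basis; `convert_inflammation_units()`
implements the bridge using the leaflet tissue properties (total area
12 cm², interstitial area 6 cm², endothelial cell volume 2×10⁻¹² L and
surface density 10⁴ cells/cm², interstitial density 5×10⁴ cells/cm², and
the foam-cell formation ratio α = 5.7×10⁻⁶ cells/g for the
oxLDL→foam-cell branch). Conversion happens once at load time, never
inside the right-hand side.

The published record for this model family prints only a handful of
parameter values (ξ, a₀, a₁, k_td, τ̄_ref, the tissue properties and the
per-case mechanical inputs). Every remaining rate constant in the shipped
file `inst/extdata/default_parameters.yaml` was therefore **calibrated by
the package authors** against the reported behavior of the system, and is
tagged `source: calibrated` to keep that provenance explicit. The
calibration targets, in order of precedence:

1. the thin (0.3 mm) reference case crosses Agatston 400 at 20.8 years —
   this anchors the product $\gamma k_c$ (a one-dimensional root find,
   `calibrate_gamma_kc()`, also available as a runtime fallback when a
   parameter file omits `gamma`/`k_c`);
2. the qualitative trajectory shapes of each pathway (oxLDL and monocyte
   transients within the first years; macrophage/foam-cell accumulation
   over decades; fast, tightly coupled NO-module dynamics; pSMAD pools
   rising toward quasi-plateaus) and the cross-thickness orderings;
3. the robustness pattern of terminal calcification: ±15% in the two
   mechanical inputs moves Ca(23 y) by under 5%, ±10% in any single rate
   constant by under 25%.

Two structural regimes were adopted during this calibration and are
deliberate design choices: TGF-β sensing is **receptor-supply-limited**
(receptor synthesis, not ligand, bounds the signaling flux at high
inflammation), and SMAD phosphorylation runs near **substrate depletion**
(SMAD synthesis is the long-run bottleneck). Both are standard saturation
mechanisms in signaling models; here they also damp the cascade's
elasticity so that small mechanical perturbations do not propagate
linearly into terminal calcification, while the large shear difference of
the pathological 0.75 mm case still falls off the PKG-activation plateau
and de-represses SMAD3. With these defaults the 0.5 mm case progresses
slightly more slowly than the 0.3 mm case: its printed averaged WSS is
higher (2.36 vs 2.23 Pa) and its strain lower, and every coupling channel
is monotone in those inputs, so the near-degeneracy of the two thinner
cases is an inherent property of this model family with these inputs.

## Numerics

* Internal time unit: seconds (the source models' rate constants are
  per-second); 23 years ≈ 7.25×10⁸ s. Output on a monthly grid by
  default.
* Stiffness: the NO module equilibrates in hours while disease evolves
  over years (rate ratio ~10⁶), so `simulate_case()` uses `deSolve`'s
  adaptive stiff-switching `lsoda` with relative tolerance 10⁻⁶ and
  per-species absolute tolerances scaled to characteristic magnitudes
  (10⁻⁹–10⁻⁸ M for concentrations, 1 Agatston for calcification).
* Quality gate: with `check_tolerance = TRUE` the run is re-integrated at
  halved tolerances and rejected if terminal calcification moves by
  ≥0.5%.
* Inside the solver, concentrations are floored at zero when evaluating
  mass-action monomials; magnitudes below the absolute tolerance may be
  transiently negative at that level. The exported right-hand-side
  functions reject states with negative entries beyond tolerance.
* Threshold crossings are linear interpolations between monthly output
  points; doubling the grid density moves the crossing times of the three
  reference cases by well under 0.1 year. There is no event-based
  stopping: all cases integrate the full horizon so trajectories stay
  comparable.
* Determinism: there is no randomness anywhere in the model, solver or
  scan; identical inputs give identical output files. The only randomness
  in the package is the synthetic field generator, which is
  seed-deterministic.

## Sensitivity analysis

`sensitivity_scan()` perturbs one quantity at a time, both signs,
re-simulates, and records
$|Ca_{pert}(23\,y) - Ca_{base}(23\,y)| / Ca_{base}(23\,y)$. The inventory
is exactly 73 quantities: 12 inflammation rates, 39 SMAD-module rates
(including $\gamma$ and $k_c$), 15 NO rates, the coupling parameters
$\xi, a_0, a_1$, the NO-fit parameters $b_0, b_1$, and the two mechanical
inputs $\bar\tau_0, \bar\epsilon_0$. Parameters move ±10%, mechanical
inputs ±15%; the reported statistic is the maximum over signs and over the
three thickness cases; failed perturbed runs are recorded as failed rows.
The baseline is computed once per case and reused. The feedback constants
$k_{td}$ and $\bar\tau_{ref}$ are treated as model structure and not
scanned. The full scan is ~440 stiff integrations and runs in a few
minutes on one CPU.

The most influential quantities under the shipped defaults are the ones
that multiply calcium production directly — $a_1$ (which enters the
exponent of $h_e$, elasticity ≈ $a_1\bar\epsilon$), $\gamma$, $k_c$ and
$a_0$ — with the SMAD3 supply rate next; this is computed, not assumed,
by the scan and the acceptance suite.

## What the synthetic field generator does and does not emulate

`generate_synthetic_fields()` produces nodal shear and strain series over
one cardiac cycle: a systole-like half-sine-squared shear burst on a small
baseline, a diastole-peaked strain plateau (leaflets bend most when
closed), node-level amplitude heterogeneity and uneven area
weights. Node amplitudes depend only on the seed and node count, so
refining the time grid refines the quadrature of the same underlying
field — which is what lets the averaging operators be checked against
dense brute-force quadrature to 10⁻⁶. The generator emulates none of the
spatial correlation structure, side asymmetry (ventricular shear is about
an order of magnitude above aortic), reversing diastolic shear, or
cycle-to-cycle variability of real FSI output; passing tests on synthetic
fields therefore validates the averaging and plumbing, not the flow
physics. Real FSI output enters through the same CSV interface
(`read_field_series()`).

## Problem sizes used by the shipped tests

The test suite integrates the three reference cases over the full 23-year
horizon on the monthly grid, runs the full 73-quantity sensitivity scan,
and exercises the mechanics oracles at 2×10⁴-node-sample densities; the
whole suite completes in a few minutes on a single CPU. Short-horizon
(2–6 year) runs are used where only plumbing is under test.

## Known limitations

* The network is a reduced inventory (25 species) built from the
  displayed balances and module descriptions of the source model family;
  it is not a reimplementation of any specific published 46-equation
  system, and its rate constants are calibrated, not measured.
* One-way coupling: mechanics evolve only through the two phenomenological
  laws; there is no re-computation of the flow field as the valve
  stiffens.
* Terminal calcification is strongly sensitive to the strain
  magnification exponent $a_1$ and to the calibrated $\gamma k_c$ product;
  conclusions should be read at the trajectory/ordering level rather than
  as patient-level predictions.
* Spatial heterogeneity (nodule location, side-specific signaling) is
  averaged away by design.
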