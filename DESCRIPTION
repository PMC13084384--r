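Package: cavdsim
Title: Mechanochemical Simulation of Calcific Aortic Valve Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates long-term calcification of aortic valve leaflets by
    coupling averaged hemodynamic inputs (wall shear stress and tissue
    strain) to a three-pathway biochemical reaction network: LDL-driven
    inflammation, TGF-beta/SMAD signaling, and shear-dependent NO/cGMP/PKG
    inhibition. Rule-declared mass-action reactions are assembled into a
    stiff ODE system whose calcification state feeds back on the effective
    mechanics through phenomenological update laws, yielding multi-decade
    Agatston-score trajectories, threshold-crossing times, and a
    one-at-a-time local sensitivity analysis over all model parameters.
    Includes tools to reduce nodal shear/strain time series from a
    fluid-structure simulation into the averaged mechanical inputs, and a
    synthetic field generator for testing that stage in isolation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
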