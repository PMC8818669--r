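Package: fusiflow
Title: Morphometry, Virtual Stenting and Hemodynamic Indices for Fusiform
    Intracranial Aneurysms
Version: 0.1.0
Authors@R: person("Fusiflow", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for fusiform intracranial aneurysms (FIA):
    cross-sectional-area profiling of vessel lumens by perpendicular ray
    casting along the centerline, detection of fusiform dilations by the
    1.5x nominal-diameter criterion, automated reconstruction of the
    pre-pathological ("healthy") vessel by radial remapping with constrained
    Laplacian smoothing, fast virtual deployment of braided flow-diverter
    stents with wire-length-conserving diameter-length coupling, boundary
    condition helpers (inflow waveform scaling, shape-based outlet flow
    splitting), and shear- and flow-related hemodynamic indices (AWSS, OSI,
    RRT, OVI, kinetic energy) computed from time-resolved wall shear stress
    and velocity fields over one cardiac cycle.  A synthetic-data module
    generates parametric fusiform vessel phantoms, a reference cardiac
    waveform and analytic Womersley pulsatile flow fields with ground truth,
    enabling fully reproducible fusiform/healthy/treated comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
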