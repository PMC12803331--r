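Package: tpvuq
Title: Sensitivity and Uncertainty Analysis of Simulated Transcatheter
    Pulmonary Valve Deployment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for studying how right ventricular outflow
    tract (RVOT) wall material uncertainty affects simulated deployment of a
    self-expanding transcatheter pulmonary valve (TPV). Implements the
    uncoupled Holzapfel-Gasser-Ogden (HGO) anisotropic hyperelastic wall
    model, a reduced-order per-station thick-walled-ring deployment solver
    with a composite-ring treatment of a transannular patch, gamma-measure
    polynomial chaos expansion (PCE) emulation with first- and total-order
    Sobol sensitivity indices, and the outcome metrics of the study:
    volume-weighted percentile stress/strain statistics, intramural strain
    profiles, mesh-layer convergence, surface-mesh distance metrics,
    perimeter-derived diameter, and regional stent enclosed volume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
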