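Package: aneuflow
Title: Wall Shear Stress and Cross-Modality Flow Comparison for Aneurysm Hemodynamics
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-processing of gridded three-component velocity fields from
    4D Flow MRI, stereoscopic and tomographic PIV, or CFD: velocity-gradient
    tensors on masked structured grids, Q-criterion vortex identification,
    inverse-distance mapping of near-wall gradients onto a triangulated lumen
    surface to estimate wall shear stress, dynamic-similarity (Reynolds)
    scaling between in-vivo and scaled in-vitro conditions, and
    resolution-matched agreement statistics (velocity normalization,
    trilinear down-sampling, line profiles, Pearson correlation,
    Bland-Altman limits of agreement).  Includes a synthetic phantom
    generator (Poiseuille pipe, aneurysm-like tube-plus-sac flow) and
    modality-degradation emulation so the whole pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
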