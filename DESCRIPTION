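Package: OCTbiometry
Title: Full-Eye OCT Biometry Under Osmotic Stress
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis of full-eye optical coherence tomography
    (OCT) biometry under osmotic stress. Provides a ground-truthed synthetic
    phantom of a layered schematic eye (mouse and model-eye geometries) imaged
    in optical-path coordinates, gradient-based surface segmentation, optical
    distortion correction by layer-wise Snell's-law ray tracing, computation of
    six biometric parameters (central corneal thickness, anterior chamber
    depth, lens thickness, cornea-retina distance, lens scattering intensity,
    iris curvature), and quantification of osmotic response dynamics
    (baseline normalization, peak change, exponential relaxation fitting,
    steady-state detection).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: Software, Visualization, BiomedicalInformatics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
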