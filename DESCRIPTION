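Package: hemotherm
Title: Multiscale Vascular Blood Flow and Bioheat Simulation on Voxelized Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Couples one-dimensional Hagen-Poiseuille flow in segmented
    arterial and venous trees with a three-dimensional two-compartment
    Darcy porous-media model of capillary perfusion on a labeled voxel
    raster. Terminal vessels exchange blood with tissue through a
    compact-support mollifier ("sphere of influence") that conserves mass
    in the unresolved microvasculature. The resulting flow field drives a
    steady-state finite-volume bioheat solver with switchable blood-tissue
    convection assumptions (Pennes-type versus counter-current exchange),
    one-at-a-time parameter sensitivity analysis, and field-comparison
    statistics. Includes synthetic fixture generators with closed-form
    oracles, sparse GMRES/ILU(0) and direct solvers, and VTK/CSV/JSON
    exports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
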