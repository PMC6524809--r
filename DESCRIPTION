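Package: aneumorph
Title: Morphometric and Hemodynamic Variability Analysis for Segmented
    Vascular Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how vessel-segmentation variability
    propagates into intracranial-aneurysm morphometry and post-processed
    hemodynamics.  Reads triangulated vascular surfaces (STL/PLY/OBJ),
    extracts lumen centerlines with maximum-inscribed-sphere radius
    profiles, detects the aneurysm ostium as the smallest separating
    planar section, isolates the sac and computes ostium area, parent
    vessel cross-sectional area, sac volume and the non-sphericity
    index, and evaluates time-resolved flow exports for time-averaged
    wall shear stress, oscillatory shear index, planar flux and neck
    inflow rate.  Ensembles of segmentations of the same vasculature
    are summarised with median / standard deviation / relative standard
    deviation tables and box-plot statistics.  A synthetic phantom
    generator with analytically known geometry and quasi-steady
    Poiseuille flow provides oracle-verifiable inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
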