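Package: murraynet
Title: Reduced-Order Hemodynamics of Murray-Law Microvascular Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds idealized bifurcating microvascular trees whose radii follow a
    generalized Murray taper, solves steady laminar Newtonian flow on them as a
    Hagen-Poiseuille hydraulic-resistance network (or by aggregating measured outlet
    flow splits up the tree), and estimates per-branch wall shear stress across
    perfusion-impairment scenarios in which subsets of outlets are occluded. Includes
    a synthetic-measurement generator emulating outlet volume-collection experiments
    with multiplicative noise and fabrication-induced radius jitter, plus occlusion
    detection and scenario comparison utilities for studying compensatory flow
    redistribution in coronary microvascular dysfunction.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
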