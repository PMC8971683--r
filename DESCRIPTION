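Package: zebraflow
Title: Microvascular Hemodynamics and Wall Shear Stress Statistics for the
    Zebrafish Trunk
Version: 0.1.0
Authors@R:
    person("Vascular", "Imaging Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying microvascular hemodynamics in the
    embryonic zebrafish trunk after tail amputation: a Poiseuille hydraulic
    model of the trunk vasculature (dorsal aorta, segmental vessels, DLAV,
    posterior cardinal vein and the embryonic circulatory loop) with discrete
    red-blood-cell transport, plasma-skimming routing at bifurcations,
    amputation, and wall-shear-stress set-point radius adaptation; a
    ground-truthed synthetic fluorescence movie generator; red-cell detection,
    coalescence and frame-to-frame linking along vessel centerlines; a
    two-regime wall-shear-stress model with per-cell occlusive resistance and
    the peak-shear-stress-portion statistic; and an Otsu multilevel-threshold
    colocalization quantifier with connected-component area filtering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
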