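Package: chipbarrier
Title: Barrier-Function Analytics for Bilayer Organ-on-Chip Plates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for high-throughput bilayer microfluidic
    (organ-on-chip) barrier co-culture experiments run in a 96-device plate
    with a 384-well interface. Provides a data model for device geometry and
    plate maps; conversion between wall shear stress and volumetric flow
    rate for laminar flow in rectangular microchannels; macromolecular
    (FITC-dextran) permeability-coefficient estimation with a
    two-compartment transport simulator and linear standard curves;
    automated quantification of endothelial coverage, nuclei and viability
    in the channel-overlap region of fluorescence micrographs;
    five-parameter-logistic immunoassay calibration and comparative-CT
    (delta-delta-Ct) qPCR fold changes; Grubbs outlier screening and Welch
    pairwise comparisons; and seeded synthetic-data generators with exact
    ground truth for every assay.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    stats,
    tibble,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
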