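Package: memripet
Title: Simultaneous PET and Manganese-Enhanced MRI Quantification of
    Beta-Cell Mass and Function
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification pipeline for simultaneous PET and
    manganese-enhanced MRI (ME-MRI) studies of the pancreatic beta cell.
    Fits longitudinal relaxation times (T1) from variable-flip-angle
    spoiled gradient-echo magnitude images, converts them to filtered
    relaxation-rate (R1) maps and manganese concentration estimates via a
    phantom-calibrated relaxivity, decay-corrects PET activity volumes to
    percent injected dose per millilitre, and correlates the two
    modalities region-wise and voxel-wise after block downsampling.
    Companion ex vivo tools quantify autoradiography sections (islet spot
    detection, islet-to-exocrine ratios, signal-versus-diameter
    regression), merge elemental mass-spectrometry-imaging maps into
    additive RGB overlays, and compute glucose-stimulated insulin
    secretion enhancement indexes. A seeded digital mouse-pancreas
    phantom generates every input modality so the full pipeline is
    testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    tiff,
    EBImage,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
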