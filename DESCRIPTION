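Package: ringtrack
Title: Automated Segmentation and Classification of Nuclear gamma-H2AX
    Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: High-content image analysis of DNA-damage phenotypes in
    fluorescence microscopy fields. Segments nuclei from the DAPI channel
    with an automatic global threshold and morphological refinement,
    filters candidate objects by area, eccentricity, circularity and
    signal intensity, and classifies each nucleus's gamma-H2AX
    distribution as discrete foci, a peripheral ring, or uniform using a
    foci-density rule and a radial-intensity quartile rule. Also computes
    per-nucleus pixelwise Pearson correlation between gamma-H2AX and
    53BP1 channels, aggregates phenotype proportions per condition, and
    ships a synthetic phantom generator with per-nucleus ground truth so
    the whole pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    stats,
    tiff,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
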