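Package: cordQuant
Title: Quantitative Fluorescence Imaging of Membrane Trafficking in C. elegans
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying fluorescence microscopy readouts of
    membrane trafficking in Caenorhabditis elegans: detection and density
    quantification of diffraction-limited puncta along the ventral nerve
    cord, two colocalization estimators (a tolerance-factor pixel-matching
    fraction with binary mask output, and a thresholded Pearson
    correlation), linear spectral unmixing of intestinal autofluorescence
    from lambda-scan stacks, kymograph-based vesicle transport metrics
    (mobile/stationary classification, direction, velocity, flux, run
    length), the accompanying summary statistics, and diagnostic-residue
    classification of Rab6 subfamily GTPases. A synthetic-microscopy data
    generator with recorded ground truth makes the full pipeline testable
    without external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tiff,
    igraph,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma,
    EBImage,
    withr,
    knitr
biocViews: CellBiology, Visualization, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
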