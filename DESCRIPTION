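Package: cryopick
Title: Template-Based Cryo-EM Particle Picking by Masked Normalized
    Cross-Correlation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic particle picking for cryo-electron micrographs by
    masked, locally normalized cross-correlation (NCC) computed with FFTs.
    Builds rotation series of templates and binary masks from base
    projections (with symmetry-aware reduction of the angular range),
    correlates each template against micrographs using a shared micrograph
    spectrum cache and FFT-friendly zero padding, reduces per-template
    correlation maps into global score and index maps by elementwise
    max/argmax under pluggable reduction topologies, and extracts picks by
    thresholding and non-maximum suppression with configurable contrast
    polarity. Includes a synthetic micrograph generator with planted
    ground-truth particles so every pipeline stage is testable without
    external data, pick-versus-reference evaluation (precision, recall,
    FDR, F-measure, mean match distance, ROC-style ranking curves), MRC2014
    image I/O, and EMAN-style box-file output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png,
    tiff
Config/testthat/edition: 3
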