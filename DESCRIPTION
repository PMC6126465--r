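Package: isomerge
Title: Isomorphism-Guided Clustering, Scaling and Merging of Multi-Crystal Diffraction Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for managing X-ray diffraction data collected from many
    crystals of the same macromolecule. Datasets are clustered on unit-cell
    parameters and annotated with the Linear Cell Variation (LCV/aLCV)
    isomorphism score; per-dataset radiation damage is detected from
    resolution-shell intensity decay and image cutoffs are suggested; usable
    resolution limits are estimated from shell-averaged signal-to-noise;
    arbitrary groups of datasets are scaled, merged and scored with standard
    quality statistics (R_merge, R_meas, R_pim, CC1/2, completeness,
    multiplicity); and an image-pruning optimiser trims damaged image tails
    to minimise R_pim under a completeness constraint. A synthetic multi-
    crystal data generator with controllable isomorphism structure, wedge
    geometry, damage and noise provides a fully reproducible test bed.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
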