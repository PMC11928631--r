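Package: dropletquant
Title: Poisson Quantification and Validation for Crude-Lysate Droplet
    Digital PCR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Absolute quantification of rare gene targets (such as T-cell
    receptor excision circles) by droplet digital PCR run directly on crude
    cell lysate. Implements droplet amplitude classification with
    blank-derived thresholds, Poisson concentration estimation with a
    corrected droplet volume, replicate merging for rare targets, assay
    validation (limit of blank, limit of detection, limit of
    quantification, intra-assay repeatability, probit hit rate), method
    agreement analysis (ordinary least squares, Spearman rank correlation,
    Bland-Altman), droplet volume estimation from monolayer micrographs,
    and a synthetic droplet-plate generator with known ground truth for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Config/testthat/edition: 3
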