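Package: refstab
Title: Reference-Gene Stability Analysis for RT-qPCR Normalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for selecting stable reference (housekeeping) genes for
    RT-qPCR normalization. Reads and quality-controls quantification-cycle
    (Cq) data with sample and assay metadata, converts Cq to relative
    quantities, ranks candidate reference genes with the geNorm pairwise
    stability measure (M values, stepwise exclusion, pairwise-variation
    V curve and optimal gene count) and the NormFinder model-based
    variance-decomposition estimator (single-group and grouped), compares
    the two rankings, performs efficiency-corrected relative quantification
    of target genes against a chosen normalizer set, and simulates
    replicate-level Cq datasets with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
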