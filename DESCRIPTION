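Package: bindsurf
Title: Nascent Transcript Binding-Surface Scoring and Nucleocytoplasmic
    Fluorescence Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how much nascent RNA "binding surface" a cell offers
    to nuclear RNA-binding proteins such as FUS, and how proteins and poly(A+)
    RNA partition between nucleus and cytoplasm. Parses HOMER-style nascent
    transcript peak tables, normalizes read counts to 10 million aligned
    reads, filters low-score peaks, computes log2(peak score x transcript
    length) binding surface scores, subsets CLIP-defined target genes, and
    compares conditions with empirical CDFs and Mann-Whitney rank-sum tests.
    For microscopy, computes per-cell integrated densities from label masks,
    background-adjusts them against a staining-free ROI, derives
    cytoplasmic-to-nuclear ratios, DAPI-normalized totals and nuclear poly(A+)
    concentrations, and correlates per-cell ratios between channels. A
    synthetic-data module generates peak tables and cell images with known
    ground truth so every stage is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage
Config/testthat/edition: 3
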