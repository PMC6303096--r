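Package: barcodeaudit
Title: Auditing DNA Barcode Reference Libraries for Species Diagnosability
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to audit a DNA barcode reference library (aligned COI
    sequences with specimen metadata) for species identification. Computes
    Kimura 2-parameter pairwise distances with pairwise deletion, builds
    neighbor-joining trees with nonparametric bootstrap support and midpoint
    rooting, classifies species as monophyletic, paraphyletic, polyphyletic or
    singleton, detects shared (identical) barcodes, applies cluster-based and
    haplotype-based diagnosability criteria, screens for potential cryptic
    diversity, and combines barcode diagnosability with expert morphology
    annotations into integrative identification-rate tables. A sequence
    simulator with known ground truth (species structure, introgression,
    singletons) supports end-to-end testing without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
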