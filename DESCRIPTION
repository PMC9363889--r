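Package: repshare
Title: Clonal Sharing Analysis of B-Cell Receptor Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies sharing of dominant B-cell receptor (BCR) clones
    between immune compartments (synovial tissue, synovial fluid,
    peripheral blood) from UMI-annotated AIRR rearrangement tables.
    Provides clonotype calling keyed by CDR3 plus V/J gene, depth
    standardization by random subsampling without replacement, detection
    of highly expanded clones (HECs), top-N clonal retrieval, the
    abundance-based Chao-modified Sorensen similarity index, group
    comparisons, and a calibrated multi-compartment synthetic repertoire
    generator with known ground-truth sharing for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
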