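Package: barcodegap
Title: Curation and Distance-Based Species Delimitation for DNA Barcode
    Reference Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and auditing COI DNA barcode reference
    libraries: haplotype collapsing with species-preservation guarantees,
    Kimura 2-parameter and Tamura-Nei pairwise distances under pairwise
    deletion, per-species barcode-gap summaries with bootstrap standard
    errors, recursive barcode-gap species delimitation and single-linkage
    threshold clustering, congruence classification of delimitation
    partitions against reference taxonomy (match/single/merge/split/complex),
    distance-based misidentification screening, sampling-effort regression,
    neighbor-joining trees with monophyly assessment, and a synthetic
    barcode-library simulator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    seqinr,
    mclust,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
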