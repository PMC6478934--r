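Package: dendricode
Title: Digital Dendrimers as Data Carriers: Path Enumeration, Barcode
    Capacity and Tandem-MS Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for working with binary-coded ("digital") dendrimers, in
    which butyl (0-bit) and hexyl (1-bit) sub-monomer units arranged on a
    branched scaffold store information at the molecular level.  Parses the
    DN/DR dendrimer notation, builds the bit-labelled rooted tree for any
    generation, enumerates the distinct binary paths of the tree by a
    deduplicated shuffle-product dynamic programme, canonicalises them into an
    encrypted data matrix, and converts the matrix into a pre-data-matrix
    barcode with its storage capacity under a configurable error-correction
    level.  A calibrated mass engine predicts MALDI-TOF precursor and MS/MS
    fragment masses for any dendrimer in the family, assigns experimental peak
    lists (CSV or MGF), and scores candidate structures for identification and
    anticounterfeiting applications.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
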