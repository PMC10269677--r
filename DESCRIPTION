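Package: methscreen
Title: Mining Stress-Resistance Regulators from Paired Bacterial m4C Methylomes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Screens a bacterial genome for candidate regulators of
    environmental stress resistance by comparing the N4-methylcytosine (m4C)
    methylome of a wild-type strain against a methyltransferase-deletion
    mutant. Computes per-gene m4C loss statistics over coding sequences and
    promoter windows, calls ORF-ordinal regions dense in a pathway category
    of interest, applies site-loss and abundance-loss thresholds to
    regulator-annotated genes, ranks the resulting candidates, and filters
    time-course differential-expression tables for cross-timepoint
    sign consistency. Includes a seeded synthetic-data generator with a
    ground-truth manifest so every stage is testable without external data,
    plus a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
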