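Package: l1deam
Title: Simulation and Analysis of APOBEC3A Deamination During LINE-1 Retrotransposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to study strand-specific cytidine deamination of transiently
    exposed single-strand DNA intermediates that arise during LINE-1 (L1)
    target-site primed reverse transcription (TPRT) and in the LEAP (L1 Element
    Amplification Protocol) in vitro assay. The package provides a mechanistic
    generative model of LEAP cDNA products and genomic L1 insertions (exposure,
    per-trinucleotide deamination, and uracil repair branches), strand-classified
    substitution calling against a reference amplicon, G-centered trinucleotide
    context accounting with availability denominators, structural annotation of
    insertions (5' truncation, inversion/deletion junctions, target-site
    duplications with mismatch attribution, coding consequences), and
    toxicity-normalized quantification of colony-count retrotransposition assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
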