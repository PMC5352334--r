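Package: msipair
Title: Microsatellite Instability Detection from Paired Tumor-Normal
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects microsatellite instability (MSI) in matched
    tumor-normal sequencing pairs. Repeat-length distributions are built
    per microsatellite locus from locus-spanning reads, quality-filtered,
    normalized, and compared with a stepwise (L1) distance; the mean
    distance over evaluable loci is the pair's instability score, called
    MSI-positive above a threshold. Includes a microsatellite scanner for
    reference genomes, a discriminative-locus ranking procedure for
    labeled cohorts, classifier evaluation with continuity-corrected
    Wilson intervals and threshold sweeps, and a deterministic simulator
    that generates reference genomes with planted repeats plus paired
    aligned reads for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
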