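Package: carpscales
Title: Two-Locus Genetics of Scale Pattern Inheritance in Common Carp
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the classical two-locus, four-allele model of scale
    pattern inheritance in common carp (Cyprinus carpio): exact Punnett-square
    phenotype expectations with the early-lethal NN class, survivor
    conditioning, enumeration of parental genotypes compatible with observed
    cross phenotypes, multinomial likelihood ranking of allele-model
    hypotheses (standard, viable-NN "weak-N", and loss-of-function "strong-s"
    variants), chi-square and exact multinomial goodness-of-fit for offspring
    count tables, cumulative fin-defect scoring and pharyngeal teeth-count
    summaries, and a signal-threshold ("rheostat") simulator that generates
    synthetic crosses with per-fish scale maps, fin states and teeth counts
    for end-to-end testing of the inference machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
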