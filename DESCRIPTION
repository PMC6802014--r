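Package: wolmlst
Title: Wolbachia MLST Typing, Coinfection Deconvolution and Host-Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Multilocus sequence typing (MLST) of Wolbachia endosymbionts from
    five-locus allele data, including allele calling from IUPAC double-peak
    mixtures, deconvolution of double infections into coinfecting sequence
    types, chimeric-allele detection, minimum-spanning sequence-type networks
    with recombinant-loop detection, Templeton-Sing nested-clade construction,
    permutation chi-square contingency batteries of infection against a nested
    mtDNA-clade hierarchy, fixed-tree marginal ancestral-state reconstruction
    of infection status under a symmetric Markov model, prevalence
    tabulations, and a synthetic-data generator with full ground truth for
    host genealogies, vertical/horizontal symbiont transmission and
    cytoplasmic-incompatibility exclusion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
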