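Package: cumira
Title: Small RNA Profiling and Exact-Test Differential Expression for
    Copper-Stress miRNA Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for two-library plant small-RNA sequencing studies:
    adapter trimming and tag collapsing, contaminant categorisation,
    known-miRNA assignment under an anchored mismatch rule, hairpin
    precursor excision and screening by the minimal folding free energy
    index (MFEI), exact Audic-Claverie differential expression between
    two libraries of unequal depth with reads-per-million normalisation,
    complementarity-based miRNA target prediction with Allen-style
    scoring, hypergeometric term enrichment, and a synthetic-data
    generator that plants hairpin loci with known expression ground
    truth.  Bundles the published count tables of a grapevine
    copper-stress study as worked-example fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    graphics,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
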