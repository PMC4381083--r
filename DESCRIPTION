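Package: codontrade
Title: Trade-Offs Between Codon Translation Times and mRNA Secondary
    Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-scale analysis of the trade-off between
    tRNA-abundance-based codon translation times and local mRNA secondary
    structure. Extracts regions of consecutively high or low structure from
    experimental per-nucleotide scores (PARS-style) or predicted
    sliding-window minimum free energy, maps codon translation-time tables
    onto transcripts, computes the difference in median codon translation
    time between structure classes with rank-based tests, builds randomized
    genome null models (synonymous codon shuffling and whole-codon
    shuffling), correlates per-gene trade-off scores with measured
    expression of synonymous variant libraries, and generates synthetic
    genomes with planted structure-codon coupling for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
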