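Package: mitoprofile
Title: Characterization Statistics for Annotated Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the standard descriptive analysis of an annotated
    vertebrate mitochondrial genome: region-wise base composition and AT/GC
    strand skew, codon usage and relative synonymous codon usage (RSCU) under
    the vertebrate mitochondrial genetic code with inference of initiation and
    (possibly incomplete) termination codons, gene-boundary overlap and
    intergenic-spacer accounting, and pairwise Ka/Ks selection screening by the
    Nei-Gojobori (1986) counting method with Jukes-Cantor correction. Includes
    a seeded synthetic mitogenome generator with recorded ground truth, readers
    and writers for GenBank flat files and a simple feature-table dialect, and
    a supermatrix exporter for downstream phylogenetics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
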