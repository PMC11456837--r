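Package: ThermoGx
Title: Comparative Genomics and Photophysiology of Thermophilic Synechococcus
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing temperature adaptation in thermophilic
    Synechococcus A/B cyanobacteria and similar clade-structured bacterial
    systems. Provides genome and proteome composition statistics (GC and
    codon-position GC, purine content, non-coding fraction, amino-acid and
    dipeptide-context frequencies, IVYWREL), protein ortholog clustering with
    clade core and clade-unique gene calling, fragment-based average
    nucleotide identity, distance-based phylogenomics with gene concordance
    factors and internode certainty, GC3-outlier scans for horizontally
    transferred genes, Nei-Gojobori dN/dS, phylogenetic generalized least
    squares with an Ornstein-Uhlenbeck correlation structure, and fitting of
    photosynthesis-irradiance (Platt), growth and oxygen-evolution data.
    Includes a seeded synthetic-data generator that emulates a thermal
    gradient of clades so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    rtracklayer,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
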