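Package: lncpair
Title: Pairing Microbiota-Responsive Long Non-Coding RNAs with Neighboring
    Protein-Coding Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for calling cis lncRNA/protein-coding gene (PCG) pairs from
    tissue-level RNA-seq quantifications of conventional versus germ-free
    mice. The pipeline applies FPKM expression and Benjamini-Hochberg FDR
    thresholds, collapses GTF transcript records into strand-aware gene
    models, classifies each lncRNA into a genomic region relative to the
    nearest PCG (5 kb upstream of the TSS through 1 kb downstream of the
    TTS), calls proximity pairs with co-regulation direction categories,
    partitions expressed and differentially regulated gene sets across
    tissues, and screens lncRNA-mRNA duplexes with a normalized
    free-energy statistic (ndG) under the -0.08 binding threshold. A
    synthetic-data generator with machine-readable planted truth supports
    download-free end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
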