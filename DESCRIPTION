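Package: bsdiverge
Title: Comparative Bisulfite-Sequencing Methylome Analysis with Built-In
    Synthetic Benchmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for comparative whole-genome bisulfite
    sequencing (BS-Seq) studies of related plant lines: three-letter
    bisulfite-aware paired-end alignment with clonal-duplicate removal,
    calibrated binomial methylcytosine calling using an unmethylated
    chloroplast control, strand-resolved homozygous SNP genotyping from
    bisulfite reads, NlaIII-anchored digital gene expression (DGE) tag
    quantification, region and metagene methylation metrics, methylation /
    genomic / expression divergence trees, and identification of
    differentially methylated genes between two groups of samples.  A
    built-in synthetic-data generator produces a miniature four-sample
    study (genome, annotations, truth tables, bisulfite reads and DGE
    tags) so that every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    ape,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
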