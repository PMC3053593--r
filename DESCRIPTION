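Package: utrsnp
Title: Targeted SNP Discovery in Duplicated Genomes from 3'UTR Amplicons and EST Mining
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for targeted discovery of single-nucleotide and small
    deletion-insertion polymorphisms in genes of partially tetraploid
    species, where recent genome duplication leaves many near-identical
    paralogs. Implements a 3'UTR-primed strategy that designs PCR
    amplicons inside the weakly conserved 3' untranslated region of
    annotated full-length cDNAs, an in silico candidate-SNP mining
    stage over EST-to-cDNA alignments with end-trim, simple-repeat and
    paralog filters, and validation of candidates in a small diploid
    panel with exclusion of paralogous sequence variants by a
    Hardy-Weinberg heterozygote-excess rule. Includes a synthetic-data
    generator for duplicated targets, diploid panels and error-bearing
    ESTs, primer design with nearest-neighbor melting temperatures,
    VCF/TSV variant output, and the pipeline's summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    BiocGenerics,
    optparse,
    knitr
Config/testthat/edition: 3
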