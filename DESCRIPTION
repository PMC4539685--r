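Package: trnaflux
Title: Codon Usage, Selfish-Element Copy Number and tRNA Gene
    Amplification in Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the coevolution of codon usage and tRNA
    gene copy number in bacterial strain complexes. Computes per-amino-acid
    relative codon usage from annotated genomes, fold enrichment of codons
    in gene subsets (selfish genetic elements, laterally transferred genes)
    against the genome-wide background with cross-strain confidence
    intervals and a rank-sum permutation test, similarity-based gene
    copy-number detection at strict identity/coverage thresholds with
    paralog clustering, tandem-array detection and phage-versus-host
    flanking-context classification, anticodon-level tRNA copy-number
    profiles with Mann-Whitney group tests, assignment of laterally
    transferred genes to phylogenetic nodes from presence/absence data, and
    correlation of codon use with tRNA gene number via phylogenetically
    independent contrasts. Includes a synthetic annotated-genome generator
    with machine-readable truth sets so every stage of the pipeline can be
    validated without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
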