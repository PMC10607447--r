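Package: PhageRecode
Title: Detection of Stop-Codon Reassignment and Comparative Genomics for
    Bacteriophage Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects alternative genetic codes in bacteriophage genomes from
    interrupted-ORF rescue and suppressor-tRNA evidence, re-annotates genomes
    under the recommended translation table (e.g. table 15, TAG to glutamine),
    and places genomes into species and genus groups using pairwise nucleotide
    identity, normalized translated similarity (SG) and VIRIDIC-style
    intergenomic similarity with threshold clustering. Includes a synthetic
    phage-genome simulator with ground-truth annotations for validation, a
    lightweight structural tRNA detector with suppressor classification, and
    reciprocal-best-hit orthology with synteny scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Annotation, Alignment, ComparativeGenomics, Metagenomics,
    SequenceMatching, Software
RoxygenNote: 7.3.3
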