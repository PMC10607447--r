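## Independent alignment-identity oracle: full Needleman-Wunsch via
## Biostrings with the same scoring scheme as the package aligner,
## identity extracted from the alignment strings with terminal overhang
## columns excluded and internal gap columns counted as mismatches.
oracleNI <- function(a, b) {
    sm <- Biostrings::nucleotideSubstitutionMatrix(match = 10, mismatch = -9)
    pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(a), Biostrings::DNAString(b),
        substitutionMatrix = sm, gapOpening = 25, gapExtension = 6,
        type = "global")
    s1 <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
    s2 <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
    gap <- s1 == "-" | s2 == "-"
    n <- length(s1)
    lead <- which(!gap)[1L] - 1L
    trail <- n - max(which(!gap))
    keep <- (lead + 1L):(n - trail)
    sum(s1[keep] == s2[keep] & !gap[keep]) / length(keep)
}

## Uniform random DNA of length n under a private seed.
randomDna <- function(n, seed) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## A gene string: ATG + (lenAa - 1) sense codons + TAA, with optional TAG
## codons written in at the given protein codon indices.
makeGene <- function(lenAa, ambersAt = integer(), seed = 1) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    sense <- PhageRecode:::SENSE_CODONS
    codons <- c("ATG", sample(sense, lenAa - 1L, replace = TRUE))
    codons[ambersAt] <- "TAG"
    paste(c(codons, "TAA"), collapse = "")
}

## All 64 codons in a fixed order.
allCodons <- function() {
    b <- c("A", "C", "G", "T")
    as.vector(outer(outer(b, b, paste0), b, paste0))
}
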