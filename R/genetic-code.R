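#' @useDynLib PhageRecode, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom stats cor runif setNames hclust cutree as.dist
#' @importFrom utils write.table read.table packageVersion
NULL

#' Genetic-code table
#'
#' A thin S4 wrapper around an NCBI translation table, restricted to the
#' three tables relevant to phage stop-codon reassignment: 11 (bacterial
#' standard), 15 (TAG decoded as glutamine) and 4 (TGA decoded as
#' tryptophan).
#'
#' @slot tableId integer NCBI table number (11, 15 or 4).
#' @slot codonToAa named character vector over all 64 codons; stops are "*".
#' @slot stopCodons character vector, subset of TAA/TAG/TGA.
#' @export
setClass("GeneticCode",
    representation(tableId = "integer",
                   codonToAa = "character",
                   stopCodons = "character"))

setValidity("GeneticCode", function(object) {
    msg <- character()
    if (length(object@codonToAa) != 64L)
        msg <- c(msg, "codonToAa must cover all 64 codons")
    if (!all(object@stopCodons %in% c("TAA", "TAG", "TGA")))
        msg <- c(msg, "stopCodons must be a subset of TAA/TAG/TGA")
    if (!identical(sort(names(which(object@codonToAa == "*"))),
                   sort(object@stopCodons)))
        msg <- c(msg, "stopCodons inconsistent with codonToAa")
    if (length(msg)) msg else TRUE
})

setMethod("show", "GeneticCode", function(object) {
    cat("GeneticCode table", object@tableId,
        " stops:", paste(object@stopCodons, collapse = ","), "\n")
})

SUPPORTED_TABLES <- c(11L, 15L, 4L)

#' Construct a genetic code
#'
#' Codon assignments are seeded from NCBI tables as shipped with Biostrings,
#' then expressed in DNA alphabet with stops as \code{"*"}.
#'
#' @param tableId NCBI translation table id: 11, 15 or 4.
#' @return A \linkS4class{GeneticCode}.
#' @examples
#' gc15 <- geneticCode(15)
#' codonTable(gc15)[["TAG"]]   # "Q"
#' @export
geneticCode <- function(tableId) {
    tableId <- as.integer(tableId)
    if (!tableId %in% SUPPORTED_TABLES)
        stop("unsupported translation table: ", tableId,
             " (supported: ", paste(SUPPORTED_TABLES, collapse = ", "), ")")
    map <- Biostrings::getGeneticCode(as.character(tableId), as.data.frame = FALSE)
    names(map) <- chartr("U", "T", names(map))
    stops <- sort(names(map)[map == "*"])
    new("GeneticCode", tableId = tableId, codonToAa = map, stopCodons = stops)
}

#' @describeIn geneticCode Accessor: the 64-codon amino-acid map.
#' @param code A GeneticCode.
#' @export
codonTable <- function(code) code@codonToAa

#' @describeIn geneticCode Accessor: stop codons of the table.
#' @export
stopCodons <- function(code) code@stopCodons

#' @describeIn geneticCode Accessor: NCBI table id.
#' @export
tableId <- function(code) code@tableId

#' Translation table reassigning a given stop codon
#'
#' Maps a stop codon to the NCBI table under which it is a sense codon:
#' TAG -> 15 (Gln), TGA -> 4 (Trp). No standard table reassigns only TAA;
#' \code{NA} is returned for it.
#'
#' @param stopCodon One of "TAG", "TGA", "TAA".
#' @return Integer table id or NA.
#' @export
reassignmentTable <- function(stopCodon) {
    switch(stopCodon, TAG = 15L, TGA = 4L, TAA = NA_integer_,
           stop("not a stop codon: ", stopCodon))
}

## Split a DNA string into its codons (character vector). No validation.
splitCodons <- function(seq) {
    n <- nchar(seq) %/% 3L
    if (n == 0L) return(character())
    starts <- seq.int(1L, by = 3L, length.out = n)
    substring(seq, starts, starts + 2L)
}

#' Translate a coding sequence
#'
#' Translates an in-frame CDS under a given genetic code. Codons containing
#' N translate to \code{"X"}; stop codons render as \code{"*"} unless
#' \code{toFirstStop} is TRUE, in which case translation halts before the
#' first stop. Reassigned codons (e.g. TAG under table 15) render as their
#' amino acid.
#'
#' @param seq DNA string (character), length divisible by 3.
#' @param code A \linkS4class{GeneticCode}.
#' @param toFirstStop Stop translating at the first stop codon?
#' @return Amino-acid string.
#' @examples
#' translateCDS("ATGCAGTAGGGCTAA", geneticCode(11))  # "MQ*G*"
#' translateCDS("ATGCAGTAGGGCTAA", geneticCode(15))  # "MQQG*"
#' @export
translateCDS <- function(seq, code, toFirstStop = FALSE) {
    if (nchar(seq) %% 3L != 0L)
        stop("sequence length not divisible by 3 (trailing partial codon)")
    codons <- splitCodons(toupper(seq))
    aa <- unname(codonTable(code)[codons])
    aa[is.na(aa)] <- "X"   # codons containing N (validated alphabet upstream)
    if (toFirstStop) {
        hit <- which(aa == "*")
        if (length(hit)) aa <- aa[seq_len(hit[1L] - 1L)]
    }
    paste(aa, collapse = "")
}

#' Reverse complement of a DNA string
#'
#' Character-level convenience wrapper (Watson-Crick complement, reversed;
#' N maps to N). For Biostrings objects use
#' \code{Biostrings::reverseComplement} directly.
#'
#' @param seq DNA string over A,C,G,T,N (case-insensitive).
#' @return Reverse-complemented string, uppercase.
#' @export
revComp <- function(seq) {
    if (nchar(seq) == 0L) return("")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}
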