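#' Read phage genomes from FASTA
#'
#' Reads a (multi-)FASTA file into a \code{DNAStringSet}. Sequences are
#' normalized to uppercase and U is converted to T. The returned set carries
#' per-genome metadata columns \code{topology} (\code{"linear"} or
#' \code{"circular"}) and \code{description} (the FASTA header text after
#' the first whitespace). A header containing the token \code{[topology=circular]}
#' or the word \code{circular} sets the topology flag.
#'
#' Ambiguity characters other than N are rejected: assembled phage contigs
#' rarely carry them and excluding them keeps codon logic exact.
#'
#' @param path Path to a FASTA file.
#' @param topology Default topology for records whose header does not
#'   declare one.
#' @return A \code{DNAStringSet} with mcols \code{topology}, \code{description}.
#' @export
readGenomes <- function(path, topology = c("linear", "circular")) {
    topology <- match.arg(topology)
    if (!file.exists(path)) stop("file not found: ", path)
    raw <- Biostrings::readBStringSet(path)
    if (length(raw) == 0L) stop("empty FASTA file: ", path)
    headers <- names(raw)
    ids <- sub("\\s.*$", "", headers)
    desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
    if (anyDuplicated(ids)) {
        dup <- unique(ids[duplicated(ids)])
        stop("duplicate sequence id(s): ", paste(dup, collapse = ", "))
    }
    seqs <- toupper(chartr("Uu", "Tt", as.character(raw)))
    bad <- regexpr("[^ACGTN]", seqs)
    if (any(bad > 0L)) {
        i <- which(bad > 0L)[1L]
        stop("non-IUPAC/ambiguity character '",
             substring(seqs[i], bad[i], bad[i]),
             "' in record '", ids[i], "' at position ", bad[i])
    }
    if (any(nchar(seqs) == 0L))
        stop("zero-length sequence: ", ids[which(nchar(seqs) == 0L)[1L]])
    topo <- ifelse(grepl("circular", headers, ignore.case = TRUE),
                   "circular", topology)
    genomes <- Biostrings::DNAStringSet(seqs)
    names(genomes) <- ids
    S4Vectors::mcols(genomes) <- S4Vectors::DataFrame(topology = topo,
                                                      description = desc)
    genomes
}

#' Write genomes to FASTA
#'
#' @param genomes A named \code{DNAStringSet}.
#' @param path Output path.
#' @param width Line width.
#' @return Invisibly, \code{path}.
#' @export
writeGenomes <- function(genomes, path, width = 70L) {
    Biostrings::writeXStringSet(genomes, path, width = width)
    invisible(path)
}

## Topology of one genome inside a set read by readGenomes (defaults linear).
genomeTopology <- function(genomes, id) {
    mc <- S4Vectors::mcols(genomes)
    if (is.null(mc) || !"topology" %in% colnames(mc)) return("linear")
    as.character(mc[id == names(genomes), "topology"][1L])
}

## Coerce a single-genome argument (DNAStringSet of 1, DNAString or string)
## to a list(id, seq [character], topology).
asGenome <- function(x, id = "genome", topology = "linear") {
    if (is(x, "DNAStringSet")) {
        stopifnot(length(x) == 1L)
        topo <- genomeTopology(x, names(x)[1L])
        list(id = names(x)[1L] %||% id, seq = as.character(x[[1L]]),
             topology = topo %||% topology)
    } else if (is(x, "DNAString")) {
        list(id = id, seq = as.character(x), topology = topology)
    } else if (is.character(x) && length(x) == 1L) {
        list(id = id, seq = toupper(x), topology = topology)
    } else stop("cannot interpret object of class ", class(x)[1L], " as a genome")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a[1L])) b else a
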