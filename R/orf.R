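#' Per-genome annotation container
#'
#' Holds the ORF and tRNA calls for one genome together with the translation
#' table used for the final annotation. ORFs and tRNAs are \code{GRanges}
#' (1-based inclusive coordinates on the forward strand, feature strand in
#' \code{strand()}), sorted by start.
#'
#' @slot genomeId character(1).
#' @slot genomeLength integer(1).
#' @slot orfs GRanges with mcols \code{frame}, \code{table_id},
#'   \code{length_aa}, \code{protein}, \code{n_reassigned_stops},
#'   \code{reassigned_starts} (IntegerList of forward-strand leftmost base
#'   positions, 1-based, of internal codons that are stops under table 11
#'   but sense under \code{table_id}), \code{wraps} (logical; TRUE for
#'   features crossing the origin of a circular genome, whose end coordinate
#'   then exceeds the genome length).
#' @slot trnas GRanges with mcols \code{anticodon}, \code{decoded_codon},
#'   \code{is_suppressor}, \code{suppressed_stop}, \code{source}, \code{score}.
#' @slot tableId integer(1) translation table of the annotation.
#' @export
setClass("PhageAnnotation",
    representation(genomeId = "character", genomeLength = "integer",
                   orfs = "GRanges", trnas = "GRanges", tableId = "integer"))

setValidity("PhageAnnotation", function(object) {
    msg <- character()
    o <- object@orfs
    if (length(o)) {
        if (is.unsorted(GenomicRanges::start(o)))
            msg <- c(msg, "orfs must be sorted by start")
        if (any(GenomicRanges::start(o) < 1L))
            msg <- c(msg, "orf start below 1")
        wraps <- S4Vectors::mcols(o)$wraps
        ok_end <- GenomicRanges::end(o) <= object@genomeLength |
            (if (is.null(wraps)) FALSE else wraps)
        if (!all(ok_end))
            msg <- c(msg, "non-wrapping orf end beyond genome length")
        if (object@tableId == 11L &&
            any(S4Vectors::mcols(o)$n_reassigned_stops > 0L))
            msg <- c(msg, "reassigned stops present under table 11")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "PhageAnnotation", function(object) {
    n_re <- sum(S4Vectors::mcols(object@orfs)$n_reassigned_stops > 0L)
    cat("PhageAnnotation for", object@genomeId,
        sprintf("(%d bp, table %d)\n", object@genomeLength, object@tableId))
    cat(sprintf("  %d ORFs (%d with internal reassigned stops), %d tRNAs\n",
                length(object@orfs), n_re, length(object@trnas)))
})

#' @describeIn PhageAnnotation ORF calls as GRanges.
#' @param annotation A PhageAnnotation.
#' @export
orfs <- function(annotation) annotation@orfs

#' @describeIn PhageAnnotation tRNA calls as GRanges.
#' @export
trnas <- function(annotation) annotation@trnas

#' @describeIn PhageAnnotation Translation table used.
#' @export
annotationTable <- function(annotation) annotation@tableId

TABLE11_STOPS <- c("TAA", "TAG", "TGA")

## Scan one coding strand of a sequence: per frame, codon classification.
## Returns list per frame: pos (1-based codon start on this strand),
## codon, is_stop (under `code`), is_start, is_t11_stop.
scanFrames <- function(seq, code, startCodons) {
    L <- nchar(seq)
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    lapply(0:2, function(f) {
        if (L - f < 3L)
            return(list(pos = integer(), codon = character(),
                        is_stop = logical(), is_start = logical(),
                        is_t11_stop = logical()))
        p <- seq.int(f + 1L, L - 2L, by = 3L)
        codon <- paste0(chars[p], chars[p + 1L], chars[p + 2L])
        list(pos = p, codon = codon,
             is_stop = codon %in% stopCodons(code),
             is_start = codon %in% startCodons,
             is_t11_stop = codon %in% TABLE11_STOPS)
    })
}

## ORFs on one coding strand; coordinates are 1-based on that strand.
## Returns a data.frame. `L_real` is the unpadded genome length (for
## circular genomes `seq` is the doubled sequence).
orfsOneStrand <- function(seq, code, minLengthAa, startCodons, overlapPolicy,
                          circular = FALSE, L_real = nchar(seq)) {
    frames <- scanFrames(seq, code, startCodons)
    out <- vector("list", 64L); k <- 0L
    for (f in 0:2) {
        fr <- frames[[f + 1L]]
        stop_idx <- which(fr$is_stop)
        if (!length(stop_idx)) next
        start_idx <- which(fr$is_start)
        prev <- 0L
        for (b in stop_idx) {
            cand <- start_idx[start_idx > prev & start_idx < b]
            prev <- b
            if (!length(cand)) next
            if (overlapPolicy == "longest_per_stop") cand <- cand[1L]
            for (a in cand) {
                len_aa <- b - a
                if (len_aa < minLengthAa) next
                s1 <- fr$pos[a]
                if (circular && s1 > L_real) next  # duplicate in doubled copy
                inner <- if (b > a + 1L) seq.int(a + 1L, b - 1L) else integer()
                re <- inner[fr$is_t11_stop[inner] & !fr$is_stop[inner]]
                aa <- unname(codonTable(code)[fr$codon[a:(b - 1L)]])
                aa[is.na(aa)] <- "X"
                k <- k + 1L
                out[[k]] <- list(start = s1, end = fr$pos[b] + 2L, frame = f,
                                 protein = paste(aa, collapse = ""),
                                 length_aa = len_aa,
                                 reassigned = fr$pos[re])
            }
        }
    }
    if (k == 0L) {
        df <- data.frame(start = integer(), end = integer(),
                         frame = integer(), protein = character(),
                         length_aa = integer())
        df$reassigned <- list()
        return(df)
    }
    df <- data.frame(start = vapply(out[1:k], `[[`, 1L, "start"),
                     end = vapply(out[1:k], `[[`, 1L, "end"),
                     frame = vapply(out[1:k], `[[`, 1L, "frame"),
                     protein = vapply(out[1:k], `[[`, "", "protein"),
                     length_aa = vapply(out[1:k], `[[`, 1L, "length_aa"))
    df$reassigned <- lapply(out[1:k], `[[`, "reassigned")
    df
}

#' Call open reading frames under a genetic code
#'
#' Deterministic six-frame ORF caller: an ORF runs from a start codon to the
#' next in-frame stop codon of \code{code} (stop included in the
#' coordinates, excluded from the protein). With
#' \code{overlapPolicy = "longest_per_stop"} (default) only the longest ORF
#' ending at each stop is kept. ORFs truncated by the end of a linear genome
#' are discarded; on circular genomes scanning uses a virtually doubled
#' sequence so origin-spanning ORFs are recovered (flagged \code{wraps},
#' end coordinate beyond the genome length).
#'
#' Internal codons that are stops under the bacterial standard table 11 but
#' sense under \code{code} (e.g. TAG under table 15) are recorded per ORF in
#' \code{reassigned_starts}/\code{n_reassigned_stops}.
#'
#' @param genome A one-record \code{DNAStringSet}, \code{DNAString} or string.
#' @param code A \linkS4class{GeneticCode} (default table 11).
#' @param minLengthAa Minimum protein length in amino acids (>= 10).
#' @param startCodons Allowed start codons.
#' @param overlapPolicy \code{"longest_per_stop"} or \code{"keep_all"}.
#' @return \code{GRanges} of ORF calls sorted by start (see
#'   \linkS4class{PhageAnnotation} for the metadata columns).
#' @export
findOrfs <- function(genome, code = geneticCode(11),
                     minLengthAa = 30L,
                     startCodons = c("ATG", "GTG", "TTG"),
                     overlapPolicy = c("longest_per_stop", "keep_all")) {
    overlapPolicy <- match.arg(overlapPolicy)
    if (minLengthAa < 10L) stop("minLengthAa must be >= 10")
    g <- asGenome(genome)
    L <- nchar(g$seq)
    circular <- identical(g$topology, "circular")
    fwd <- if (circular) paste0(g$seq, g$seq) else g$seq
    rev <- revComp(fwd)

    plus <- orfsOneStrand(fwd, code, minLengthAa, startCodons, overlapPolicy,
                          circular = circular, L_real = L)
    minus <- orfsOneStrand(rev, code, minLengthAa, startCodons, overlapPolicy,
                           circular = circular, L_real = L)
    Ls <- nchar(fwd)
    ## map minus-strand (coords on revcomp) to forward coordinates
    if (nrow(minus)) {
        s <- Ls - minus$end + 1L
        e <- Ls - minus$start + 1L
        minus$start <- s; minus$end <- e
        minus$reassigned <- lapply(minus$reassigned,
                                   function(p) sort(Ls - (p + 2L) + 1L))
        if (circular) {
            ## canonicalize into [1, L]
            shift <- ifelse(minus$start > L, L, 0L)
            minus$start <- minus$start - shift
            minus$end <- minus$end - shift
            minus$reassigned <- Map(function(p, sh) p - sh,
                                    minus$reassigned, shift)
            keep <- !duplicated(minus[c("start", "end")])
            minus <- minus[keep, , drop = FALSE]
        }
    }
    plus$strand <- rep("+", nrow(plus))
    minus$strand <- rep("-", nrow(minus))
    df <- rbind(plus, minus)
    if (circular && nrow(df)) {
        ## drop duplicates that appear fully within the second copy
        keep <- df$start <= L
        df <- df[keep, , drop = FALSE]
        df <- df[!duplicated(df[c("start", "end", "strand")]), , drop = FALSE]
    }
    if (!nrow(df)) {
        gr <- GenomicRanges::GRanges()
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            frame = integer(), table_id = integer(), length_aa = integer(),
            protein = character(), n_reassigned_stops = integer(),
            reassigned_starts = IRanges::IntegerList(),
            wraps = logical())
        return(gr)
    }
    o <- order(df$start, df$end)
    df <- df[o, , drop = FALSE]
    gr <- GenomicRanges::GRanges(
        seqnames = g$id,
        ranges = IRanges::IRanges(start = df$start, end = df$end),
        strand = df$strand,
        frame = df$frame,
        table_id = tableId(code),
        length_aa = df$length_aa,
        protein = df$protein,
        n_reassigned_stops = lengths(df$reassigned),
        reassigned_starts = IRanges::IntegerList(df$reassigned),
        wraps = df$end > L)
    gr
}

#' Fraction of a genome covered by ORFs
#'
#' Union of ORF intervals, both strands projected onto forward coordinates,
#' divided by genome length. Wrapping features of circular genomes are
#' counted modulo the genome length.
#'
#' @param orfGr GRanges of ORF calls (from \code{\link{findOrfs}}).
#' @param genomeLength Genome length in bp.
#' @return Fraction in [0, 1].
#' @export
codingFraction <- function(orfGr, genomeLength) {
    if (genomeLength <= 0L) stop("genomeLength must be positive")
    if (!length(orfGr)) return(0)
    r <- IRanges::ranges(orfGr)
    s <- IRanges::start(r); e <- IRanges::end(r)
    ## fold wrap-overhang back to the origin
    over <- e > genomeLength
    parts <- IRanges::IRanges(start = c(s, rep(1L, sum(over))),
                              end = c(pmin(e, genomeLength),
                                      e[over] - genomeLength))
    covered <- sum(IRanges::width(IRanges::reduce(parts)))
    min(1, covered / genomeLength)
}

#' Assemble a PhageAnnotation
#'
#' @param genome Genome (string/DNAString/one-record DNAStringSet).
#' @param orfGr GRanges of ORFs.
#' @param trnaGr GRanges of tRNAs (optional).
#' @param tableId Translation table of the annotation.
#' @return A \linkS4class{PhageAnnotation}.
#' @export
phageAnnotation <- function(genome, orfGr,
                            trnaGr = GenomicRanges::GRanges(),
                            tableId = 11L) {
    g <- asGenome(genome)
    new("PhageAnnotation", genomeId = g$id,
        genomeLength = nchar(g$seq),
        orfs = orfGr, trnas = trnaGr, tableId = as.integer(tableId))
}
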