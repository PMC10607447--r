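## Watson-Crick + G.U wobble pairing on DNA characters.
PAIR_OK <- local({
    m <- matrix(FALSE, 5, 5,
                dimnames = list(c("A","C","G","T","N"), c("A","C","G","T","N")))
    m["A","T"] <- m["T","A"] <- TRUE
    m["G","C"] <- m["C","G"] <- TRUE
    m["G","T"] <- m["T","G"] <- TRUE
    m
})

basePairs <- function(x, y) {
    x[!x %in% rownames(PAIR_OK)] <- "N"
    y[!y %in% rownames(PAIR_OK)] <- "N"
    PAIR_OK[cbind(x, y)]
}

#' Classify a tRNA anticodon as suppressor
#'
#' A tRNA is a stop-codon suppressor when its anticodon base-pairs with a
#' stop codon: anticodon CTA decodes TAG (amber), TCA decodes TGA (opal),
#' TTA decodes TAA (ochre). Anticodons are given 5'->3' in DNA alphabet as
#' they read on the coding strand; the decoded codon is the reverse
#' complement.
#'
#' @param anticodon 3-nt DNA string.
#' @return List with \code{is_suppressor} (logical), \code{suppressed_stop}
#'   ("TAG"/"TGA"/"TAA"/"none") and \code{decoded_codon}.
#' @examples
#' classifySuppressor("CTA")  # amber suppressor
#' @export
classifySuppressor <- function(anticodon) {
    anticodon <- toupper(anticodon)
    if (nchar(anticodon) != 3L || grepl("[^ACGT]", anticodon))
        stop("anticodon must be a 3-nt string over A/C/G/T, got: ", anticodon)
    decoded <- revComp(anticodon)
    sup <- decoded %in% TABLE11_STOPS
    list(is_suppressor = sup,
         suppressed_stop = if (sup) decoded else "none",
         decoded_codon = decoded)
}

## Canonical-numbering offsets of the detector/simulator cloverleaf
## (0-based from the tRNA 5' end; delta = variable-loop length - 5).
TRNA_LAYOUT <- list(
    acc5 = 0:6,            # pairs acc3 (reversed)
    dstem5 = 9:12,         # pairs 21:24 reversed
    acstem5 = 26:30,       # pairs 38:42 reversed
    anticodon = 33:35,
    tstem5 = function(d) 48:52 + d,
    tloop_ttc = function(d) 53:55 + d,
    tstem3 = function(d) 60:64 + d,
    acc3 = function(d) 65:71 + d)

## Scan one strand (1-based positions on that strand). Returns data.frame.
scanTrnaStrand <- function(seq, deltaRange = -2:10) {
    n <- nchar(seq)
    if (n < 80L) return(NULL)
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    maxd <- max(deltaRange)
    tmax <- n - (71L + maxd + 1L)
    if (tmax < 1L) tmax <- n - 72L
    if (tmax < 1L) return(NULL)
    ## anticodon-stem candidates: all 5 pairs (G.U allowed) at fixed offsets
    t <- seq_len(tmax)
    ok <- rep(TRUE, tmax)
    for (i in 0:4)
        ok <- ok & basePairs(chars[t + 26L + i], chars[t + 42L - i])
    cand <- t[ok]
    if (!length(cand)) return(NULL)
    hits <- vector("list", length(cand)); k <- 0L
    for (tt in cand) {
        ## D stem: >= 3 of 4 pairs
        dpairs <- sum(basePairs(chars[tt + 9:12], chars[tt + 24:21]))
        if (dpairs < 3L) next
        best <- NULL
        for (d in deltaRange) {
            e <- tt + 71L + d           # last base of acceptor 3' side
            if (e > n || tt + 55L + d > n) next
            acc <- sum(basePairs(chars[tt + 0:6], chars[e - 0:6]))
            if (acc < 6L) next
            tst <- sum(basePairs(chars[tt + 48:52 + d], chars[tt + 64:60 + d]))
            if (tst < 4L) next
            ttc <- paste0(chars[tt + 53:55 + d], collapse = "") == "TTC"
            if (!ttc) next
            score <- acc + tst + dpairs + 5L + 3L  # +AC stem, +TTC bonus
            if (is.null(best) || score > best$score)
                best <- list(start = tt, end = e, score = score)
        }
        if (!is.null(best)) {
            k <- k + 1L
            best$anticodon <- paste0(chars[best$start + 33:35], collapse = "")
            hits[[k]] <- best
        }
    }
    if (k == 0L) return(NULL)
    data.frame(start = vapply(hits[1:k], `[[`, 1L, "start"),
               end = vapply(hits[1:k], `[[`, 1L, "end"),
               score = vapply(hits[1:k], `[[`, 1L, "score"),
               anticodon = vapply(hits[1:k], `[[`, "", "anticodon"))
}

trnaGRanges <- function(df, genomeId) {
    if (is.null(df) || !nrow(df)) {
        gr <- GenomicRanges::GRanges()
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            anticodon = character(), decoded_codon = character(),
            is_suppressor = logical(), suppressed_stop = character(),
            source = character(), score = integer())
        return(gr)
    }
    cls <- lapply(df$anticodon, function(a)
        if (grepl("[^ACGT]", a)) list(is_suppressor = FALSE,
                                      suppressed_stop = "none",
                                      decoded_codon = NA_character_)
        else classifySuppressor(a))
    GenomicRanges::GRanges(
        seqnames = genomeId,
        ranges = IRanges::IRanges(df$start, df$end),
        strand = df$strand,
        anticodon = df$anticodon,
        decoded_codon = vapply(cls, `[[`, "", "decoded_codon"),
        is_suppressor = vapply(cls, `[[`, TRUE, "is_suppressor"),
        suppressed_stop = vapply(cls, `[[`, "", "suppressed_stop"),
        source = df$source,
        score = as.integer(df$score))
}

#' Detect tRNA genes with a cloverleaf heuristic
#'
#' Scans both strands for loci laid out on canonical tRNA numbering: a
#' 7-bp acceptor stem (>= 6 pairs, G.U wobble allowed), a 4-bp D stem
#' (>= 3 pairs), a 5-bp anticodon stem (all 5 pairs) enclosing a 7-nt loop
#' with the anticodon at loop positions 3-5, a 5-bp T stem (>= 4 pairs) and
#' the TTC motif opening the T loop. The variable loop may span 3-15 nt.
#' Overlapping candidates are resolved to the best score (score = paired
#' bases + motif bonuses).
#'
#' This is a deliberately lightweight detector: its sensitivity on natural
#' tRNAs with non-canonical arm lengths is limited (use
#' \code{\link{ingestExternalTrnas}} to import tRNAscan-SE calls), but
#' suppressor classification given an anticodon is exact.
#'
#' @param genome Genome (string/DNAString/one-record DNAStringSet).
#' @return GRanges of tRNA calls (see \linkS4class{PhageAnnotation}).
#' @export
detectTrnas <- function(genome) {
    g <- asGenome(genome)
    L <- nchar(g$seq)
    plus <- scanTrnaStrand(g$seq)
    minus <- scanTrnaStrand(revComp(g$seq))
    if (!is.null(plus)) plus$strand <- "+"
    if (!is.null(minus)) {
        s <- L - minus$end + 1L
        e <- L - minus$start + 1L
        minus$start <- s; minus$end <- e
        minus$strand <- "-"
    }
    df <- rbind(plus, minus)
    if (is.null(df) || !nrow(df)) return(trnaGRanges(NULL, g$id))
    df$source <- "builtin"
    ## resolve overlaps: keep best-scoring, greedy
    df <- df[order(-df$score, df$start), , drop = FALSE]
    keep <- rep(TRUE, nrow(df))
    for (i in seq_len(nrow(df))) {
        if (!keep[i]) next
        j <- which(keep & seq_len(nrow(df)) > i)
        if (length(j)) {
            ov <- df$start[j] <= df$end[i] & df$end[j] >= df$start[i]
            keep[j[ov]] <- FALSE
        }
    }
    df <- df[keep, , drop = FALSE]
    df <- df[order(df$start), , drop = FALSE]
    sort(trnaGRanges(df, g$id), ignore.strand = TRUE)
}

#' Import externally produced tRNA annotations (GFF3)
#'
#' Reads tRNA features (e.g. tRNAscan-SE output converted to GFF3) and
#' applies the same suppressor classification as the builtin detector.
#' The anticodon is taken from an \code{anticodon} attribute when present,
#' otherwise derived from an \code{anticodon_start} attribute (1-based
#' position of the anticodon's first base on the feature's coding strand),
#' otherwise the feature is skipped with a warning.
#'
#' @param gffPath Path to a GFF3 file.
#' @param genome Genome the features belong to.
#' @return GRanges of tRNA calls with \code{source = "external"}.
#' @export
ingestExternalTrnas <- function(gffPath, genome) {
    g <- asGenome(genome)
    feats <- rtracklayer::import(gffPath, format = "gff3")
    feats <- feats[tolower(as.character(feats$type)) == "trna"]
    if (!length(feats)) return(trnaGRanges(NULL, g$id))
    if (any(GenomicRanges::end(feats) > nchar(g$seq)) ||
        any(GenomicRanges::start(feats) < 1L))
        stop("tRNA feature outside genome bounds")
    mc <- S4Vectors::mcols(feats)
    anti <- rep(NA_character_, length(feats))
    acol <- intersect(c("anticodon", "Anticodon"), colnames(mc))
    if (length(acol)) anti <- toupper(as.character(mc[[acol[1L]]]))
    miss <- is.na(anti) | !grepl("^[ACGT]{3}$", anti)
    if ("anticodon_start" %in% colnames(mc)) {
        ## forward-strand leftmost base of the anticodon triplet
        as1 <- suppressWarnings(as.integer(as.character(mc$anticodon_start)))
        for (i in which(miss & !is.na(as1))) {
            tri <- substr(g$seq, as1[i], as1[i] + 2L)
            st <- as.character(GenomicRanges::strand(feats))[i]
            anti[i] <- if (st == "-") revComp(tri) else tri
        }
        miss <- is.na(anti) | !grepl("^[ACGT]{3}$", anti)
    }
    if (any(miss))
        warning(sum(miss), " tRNA feature(s) without anticodon skipped")
    keep <- !miss
    if (!any(keep)) return(trnaGRanges(NULL, g$id))
    df <- data.frame(start = GenomicRanges::start(feats)[keep],
                     end = GenomicRanges::end(feats)[keep],
                     strand = as.character(GenomicRanges::strand(feats))[keep],
                     score = 0L,
                     anticodon = anti[keep],
                     source = "external")
    df$strand[!df$strand %in% c("+", "-")] <- "+"
    sort(trnaGRanges(df, g$id), ignore.strand = TRUE)
}

#' Count suppressor tRNAs matching a stop codon
#'
#' @param trnaGr GRanges of tRNA calls.
#' @param stopCodon "TAG", "TGA" or "TAA".
#' @return Integer count.
#' @export
suppressorSupport <- function(trnaGr, stopCodon) {
    if (!length(trnaGr)) return(0L)
    sum(S4Vectors::mcols(trnaGr)$suppressed_stop == stopCodon)
}
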