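#' Per-genome stop-codon reassignment evidence and verdict
#'
#' One row of \code{stats} per candidate stop codon (TAG, TGA, TAA) with
#' the rescue statistics obtained by re-calling ORFs under the table that
#' reads that codon as sense, plus the final verdict.
#'
#' @slot genomeId character(1).
#' @slot stats data.frame, one row per candidate codon: columns
#'   \code{stop_codon}, \code{alt_table}, \code{supported} (is there an
#'   NCBI table reassigning the codon), \code{n_interruption_candidates},
#'   \code{coding_fraction_11}, \code{coding_fraction_alt},
#'   \code{coding_fraction_gain}, \code{mean_orf_length_ratio},
#'   \code{n_orfs_with_internal_stop}, \code{n_internal_stops_total},
#'   \code{suppressor_trna_support}.
#' @slot verdict list: \code{status} ("standard" or "reassigned"),
#'   \code{codon}, \code{recommended_table}, \code{notes} (character).
#' @export
setClass("RecodingReport",
    representation(genomeId = "character", stats = "data.frame",
                   verdict = "list"))

setValidity("RecodingReport", function(object) {
    g <- object@stats$coding_fraction_gain
    if (length(g) && any(g < -1 | g > 1))
        return("coding_fraction_gain outside [-1, 1]")
    TRUE
})

setMethod("show", "RecodingReport", function(object) {
    v <- object@verdict
    cat("RecodingReport for", object@genomeId, "\n")
    st <- object@stats
    for (i in seq_len(nrow(st)))
        cat(sprintf("  %s: gain=%+.4f candidates=%d orfs_with_stop=%d tRNA=%d%s\n",
                    st$stop_codon[i], st$coding_fraction_gain[i],
                    st$n_interruption_candidates[i],
                    st$n_orfs_with_internal_stop[i],
                    st$suppressor_trna_support[i],
                    if (!st$supported[i]) " (no supported table)" else ""))
    if (v$status == "reassigned")
        cat(sprintf("  verdict: reassigned(%s -> table %d)\n",
                    v$codon, v$recommended_table))
    else cat("  verdict: standard code (table 11)\n")
    if (length(v$notes)) cat("  notes:", paste(v$notes, collapse = "; "), "\n")
})

#' @describeIn RecodingReport The verdict list.
#' @param report A RecodingReport.
#' @export
verdict <- function(report) report@verdict

#' @describeIn RecodingReport The per-codon statistics table.
#' @export
recodingStats <- function(report) report@stats

## A genetic code in which `stopCodon` is read as sense. TAG -> table 15,
## TGA -> table 4. TAA has no standard NCBI table; a synthetic code
## (tableId 0, TAA read as Gln) is returned for completeness so its rescue
## statistics can still be computed.
reassignedCode <- function(stopCodon) {
    tid <- reassignmentTable(stopCodon)
    if (!is.na(tid)) return(geneticCode(tid))
    map <- codonTable(geneticCode(11))
    map["TAA"] <- "Q"
    new("GeneticCode", tableId = 0L, codonToAa = map,
        stopCodons = sort(names(map)[map == "*"]))
}

#' Find interrupted-ORF candidates for a stop codon
#'
#' Scans all six frames of the table-11 segmentation for adjacent coding
#' fragments whose separation consists only of in-frame stop codons of the
#' named type. Fragments are stop-to-stop segments; the upstream-most
#' fragment of a chain must contain a start codon at least
#' \code{minFragmentAa} codons before the interrupting stop, while
#' continuation fragments (already downstream of an interrupting stop) need
#' no start. Consecutive interrupting stops chain: each adjacent fragment
#' pair is one candidate row sharing a \code{chain_id}.
#'
#' @param genome Genome (string/DNAString/one-record DNAStringSet).
#' @param stopCodon "TAG", "TGA" or "TAA".
#' @param minFragmentAa Minimum fragment length (aa) on both sides.
#' @param startCodons Start codons anchoring the first fragment of a chain.
#' @return data.frame, one row per adjacent fragment pair: strand, frame,
#'   chain_id, up_len_aa, down_len_aa, n_joining_stops, joined_length_aa,
#'   stop_pos (forward-strand leftmost base of the first joining stop).
#' @export
findInterruptions <- function(genome, stopCodon = "TAG",
                              minFragmentAa = 15L,
                              startCodons = c("ATG", "GTG", "TTG")) {
    stopifnot(stopCodon %in% TABLE11_STOPS)
    g <- asGenome(genome)
    L <- nchar(g$seq)
    code11 <- geneticCode(11)
    rows <- list(); k <- 0L
    for (strand in c("+", "-")) {
        s <- if (strand == "-") revComp(g$seq) else g$seq
        frames <- scanFrames(s, code11, startCodons)
        for (f in 0:2) {
            fr <- frames[[f + 1L]]
            stops <- which(fr$is_stop)
            if (length(stops) < 2L) next
            type_c <- fr$codon[stops] == stopCodon
            ## segment i: codons strictly between stops[i-1] and stops[i]
            bounds <- c(0L, stops)
            segLen <- diff(bounds) - 1L          # aa length of segment i
            nSeg <- length(stops)
            ## start codon position giving >= minFragmentAa codons of ORF
            ## upstream of stop i (segment i is codons bounds[i]+1..stops[i]-1)
            segHasAnchor <- vapply(seq_len(nSeg), function(i) {
                lo <- bounds[i] + 1L; hi <- stops[i] - minFragmentAa
                hi >= lo && any(fr$is_start[lo:hi])
            }, TRUE)
            chain <- 0L
            prevWasC <- FALSE
            for (i in seq_len(nSeg - 1L)) {
                ## joining run: stops i..j all of type c with empty segments
                if (!type_c[i]) { prevWasC <- FALSE; next }
                j <- i
                while (j < nSeg && type_c[j + 1L] && segLen[j + 1L] == 0L)
                    j <- j + 1L
                if (j >= nSeg) { prevWasC <- FALSE; next }
                upOk <- segLen[i] >= minFragmentAa &&
                    (segHasAnchor[i] || prevWasC)
                downOk <- segLen[j + 1L] >= minFragmentAa
                if (upOk && downOk) {
                    if (!prevWasC) chain <- chain + 1L
                    nJoin <- j - i + 1L
                    upLen <- if (prevWasC || !segHasAnchor[i]) segLen[i]
                             else {
                                 st <- which(fr$is_start[(bounds[i] + 1L):(stops[i] - 1L)])[1L]
                                 stops[i] - (bounds[i] + st)
                             }
                    k <- k + 1L
                    sp <- fr$pos[stops[i]]          # coding-strand 1-based
                    rows[[k]] <- data.frame(
                        strand = strand, frame = f,
                        chain_id = paste0(strand, f, "_", chain),
                        up_len_aa = upLen, down_len_aa = segLen[j + 1L],
                        n_joining_stops = nJoin,
                        joined_length_aa = upLen + nJoin + segLen[j + 1L],
                        stop_pos = if (strand == "+") sp else L - (sp + 2L) + 1L)
                    prevWasC <- TRUE
                } else prevWasC <- FALSE
            }
        }
    }
    if (!k) return(data.frame(strand = character(), frame = integer(),
                              chain_id = character(), up_len_aa = integer(),
                              down_len_aa = integer(),
                              n_joining_stops = integer(),
                              joined_length_aa = integer(),
                              stop_pos = integer()))
    do.call(rbind, rows)
}

## Optimal non-overlapping ORF tiling by weighted interval scheduling,
## with quadratic length weights: maximizing sum(width^2) strongly favors
## few long ORFs over mosaics of short shadow ORFs, so real genes always
## win their span and junk enters the tiling only where nothing competes.
## The coding fraction of this tiling responds specifically to interrupted
## genes being rescued under an alternative table.
tilingOrfs <- function(orfGr) {
    n <- length(orfGr)
    if (n < 2L) return(orfGr)
    s <- GenomicRanges::start(orfGr); e <- GenomicRanges::end(orfGr)
    o <- order(e)
    s <- s[o]; e <- e[o]
    w <- as.numeric(e - s + 1L)^2
    ## p[i]: last interval (in end order) ending before s[i]
    p <- findInterval(s - 1L, e)
    M <- numeric(n + 1L)
    take <- logical(n)
    for (i in seq_len(n)) {
        with_i <- w[i] + M[p[i] + 1L]
        if (with_i > M[i]) { M[i + 1L] <- with_i; take[i] <- TRUE }
        else M[i + 1L] <- M[i]
    }
    sel <- logical(n); i <- n
    while (i >= 1L) {
        if (take[i] && M[i + 1L] == w[i] + M[p[i] + 1L]) {
            sel[i] <- TRUE; i <- p[i]
        } else i <- i - 1L
    }
    sort(orfGr[o[sel]], ignore.strand = TRUE)
}

#' Rescue statistics for one candidate stop codon
#'
#' Calls ORFs under table 11 and under the table reading \code{stopCodon}
#' as sense, reduces both to representative non-redundant sets, and
#' summarizes the genome-wide rescue signal: gain in coding fraction, mean
#' ORF-length ratio, interrupted-ORF candidates and suppressor-tRNA
#' support.
#'
#' @param genome Genome.
#' @param stopCodon "TAG", "TGA" or "TAA" (TAA is computed but flagged:
#'   no standard table reassigns it alone).
#' @param trnaGr tRNA calls (GRanges) or NULL.
#' @param minLengthAa,startCodons ORF-caller settings.
#' @param minFragmentAa Interruption fragment threshold.
#' @param orfs11 Optional precomputed table-11 ORF calls (avoids
#'   rescanning when scoring several codons on one genome).
#' @param minRescueLengthAa Minimum ORF length (aa) entering the rescue
#'   coverage statistics; longer than the caller minimum so that short
#'   spurious ORFs in intergenic spacers cannot blur the coding-fraction
#'   gain in either direction.
#' @return One-row data.frame (see \linkS4class{RecodingReport}).
#' @export
recodingScore <- function(genome, stopCodon = "TAG", trnaGr = NULL,
                          minLengthAa = 30L,
                          startCodons = c("ATG", "GTG", "TTG"),
                          minFragmentAa = 15L, minRescueLengthAa = 90L,
                          orfs11 = NULL) {
    stopifnot(stopCodon %in% TABLE11_STOPS)
    g <- asGenome(genome)
    L <- nchar(g$seq)
    altCode <- reassignedCode(stopCodon)
    minRescueLengthAa <- max(minLengthAa, minRescueLengthAa)
    if (is.null(orfs11))
        orfs11 <- findOrfs(genome, geneticCode(11), minLengthAa, startCodons)
    orfsAlt <- findOrfs(genome, altCode, minLengthAa, startCodons)
    longEnough <- function(o, n) o[S4Vectors::mcols(o)$length_aa >= n]
    rep11 <- tilingOrfs(longEnough(orfs11, minRescueLengthAa))
    repAlt <- tilingOrfs(longEnough(orfsAlt, minRescueLengthAa))
    cf11 <- codingFraction(rep11, L)
    cfAlt <- codingFraction(repAlt, L)
    mlr <- if (length(rep11))
        mean(S4Vectors::mcols(repAlt)$length_aa) /
        mean(S4Vectors::mcols(rep11)$length_aa) else NA_real_
    nre <- S4Vectors::mcols(repAlt)$n_reassigned_stops
    cand <- findInterruptions(genome, stopCodon, minFragmentAa, startCodons)
    data.frame(
        stop_codon = stopCodon,
        alt_table = tableId(altCode),
        supported = !is.na(reassignmentTable(stopCodon)),
        n_interruption_candidates = nrow(cand),
        coding_fraction_11 = cf11,
        coding_fraction_alt = cfAlt,
        coding_fraction_gain = cfAlt - cf11,
        mean_orf_length_ratio = mlr,
        n_orfs_with_internal_stop = sum(nre > 0L),
        n_internal_stops_total = sum(nre),
        suppressor_trna_support =
            if (is.null(trnaGr)) 0L else suppressorSupport(trnaGr, stopCodon))
}

#' Decide the genome's genetic code
#'
#' Applies the decision rule to the per-codon statistics: a codon is called
#' reassigned when its coding-fraction gain is at least \code{gMin} and it
#' has at least \code{kMin} interrupted-ORF candidates. Suppressor-tRNA
#' support is recorded as corroborating but not required (recoded phage
#' genomes without suppressor tRNA genes are known). If two codons pass,
#' the higher gain wins with a warning note (no standard table reassigns
#' two stops here). TAA can never be recommended (no supported table).
#'
#' @param stats data.frame of per-codon rows from \code{\link{recodingScore}}.
#' @param gMin Minimum coding-fraction gain (default 0.02).
#' @param kMin Minimum interruption-candidate count (default 5).
#' @return Verdict list: status, codon, recommended_table, notes.
#' @export
decideCode <- function(stats, gMin = 0.02, kMin = 5L) {
    notes <- character()
    pass <- stats$coding_fraction_gain >= gMin &
        stats$n_interruption_candidates >= kMin
    passSup <- pass & stats$supported
    if (any(pass & !stats$supported))
        notes <- c(notes, sprintf(
            "%s passes the rescue rule but no supported translation table reassigns it",
            paste(stats$stop_codon[pass & !stats$supported], collapse = ",")))
    if (!any(passSup))
        return(list(status = "standard", codon = NA_character_,
                    recommended_table = 11L, notes = notes))
    if (sum(passSup) > 1L)
        notes <- c(notes, "multiple codons pass; recommending the higher gain (no double-reassignment table)")
    i <- which(passSup)[which.max(stats$coding_fraction_gain[passSup])]
    if (stats$suppressor_trna_support[i] == 0L)
        notes <- c(notes, "no suppressor tRNA support (reassignment can occur without suppressor tRNA genes)")
    list(status = "reassigned", codon = stats$stop_codon[i],
         recommended_table = stats$alt_table[i], notes = notes)
}

#' Full recoding analysis of one genome
#'
#' Computes \code{\link{recodingScore}} for TAG, TGA and TAA, applies
#' \code{\link{decideCode}} and returns a \linkS4class{RecodingReport}.
#'
#' @inheritParams recodingScore
#' @inheritParams decideCode
#' @param detect Run the builtin tRNA detector when \code{trnaGr} is NULL?
#' @return A \linkS4class{RecodingReport}.
#' @export
recodingReport <- function(genome, trnaGr = NULL, detect = TRUE,
                           minLengthAa = 30L,
                           startCodons = c("ATG", "GTG", "TTG"),
                           minFragmentAa = 15L, gMin = 0.02, kMin = 5L) {
    g <- asGenome(genome)
    if (is.null(trnaGr) && detect) trnaGr <- detectTrnas(genome)
    orfs11 <- findOrfs(genome, geneticCode(11), minLengthAa, startCodons)
    stats <- do.call(rbind, lapply(TABLE11_STOPS, function(cd)
        recodingScore(genome, cd, trnaGr, minLengthAa, startCodons,
                      minFragmentAa, orfs11 = orfs11)))
    v <- decideCode(stats, gMin, kMin)
    new("RecodingReport", genomeId = g$id, stats = stats, verdict = v)
}

#' Re-annotate a genome under its recommended code
#'
#' Final ORF set under the recommended table, combined with tRNA calls into
#' a \linkS4class{PhageAnnotation}. The summary attributes record how many
#' ORFs carry at least one internal reassigned stop and their percentage.
#'
#' @param genome Genome.
#' @param code Recommended \linkS4class{GeneticCode} (e.g. from the verdict).
#' @param trnaGr tRNA calls (GRanges), optional.
#' @param minLengthAa,startCodons,overlapPolicy ORF-caller settings.
#' @param tiling Reduce to the optimal non-overlapping tiling (the
#'   package's final gene set)?
#' @return A \linkS4class{PhageAnnotation}; see \code{\link{recodedOrfStats}}.
#' @export
annotateRecoded <- function(genome, code, trnaGr = GenomicRanges::GRanges(),
                            minLengthAa = 30L,
                            startCodons = c("ATG", "GTG", "TTG"),
                            overlapPolicy = "longest_per_stop",
                            tiling = TRUE) {
    o <- findOrfs(genome, code, minLengthAa, startCodons, overlapPolicy)
    if (tiling) o <- tilingOrfs(o)
    phageAnnotation(genome, o, trnaGr, tableId = tableId(code))
}

#' Recoded-ORF summary of an annotation
#'
#' @param annotation A \linkS4class{PhageAnnotation}.
#' @return List: n_orfs, n_recoded_orfs, pct_recoded, n_internal_stops.
#' @export
recodedOrfStats <- function(annotation) {
    nre <- S4Vectors::mcols(orfs(annotation))$n_reassigned_stops
    n <- length(nre)
    list(n_orfs = n, n_recoded_orfs = sum(nre > 0L),
         pct_recoded = if (n) 100 * sum(nre > 0L) / n else 0,
         n_internal_stops = sum(nre))
}
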