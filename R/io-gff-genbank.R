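annotationToGRanges <- function(annotation) {
    o <- orfs(annotation)
    t <- trnas(annotation)
    feats <- GenomicRanges::GRanges()
    if (length(o)) {
        mo <- S4Vectors::mcols(o)
        go <- GenomicRanges::GRanges(
            seqnames = annotation@genomeId,
            ranges = IRanges::ranges(o), strand = GenomicRanges::strand(o))
        S4Vectors::mcols(go) <- S4Vectors::DataFrame(
            source = "PhageRecode", type = "CDS",
            phase = 0L,
            ID = sprintf("%s_orf%03d", annotation@genomeId, seq_along(o)),
            transl_table = as.character(mo$table_id),
            frame = as.character(mo$frame),
            reassigned_stops = vapply(
                as.list(mo$reassigned_starts),
                function(p) paste(p, collapse = ","), ""))
        feats <- go
    }
    if (length(t)) {
        mt <- S4Vectors::mcols(t)
        gt <- GenomicRanges::GRanges(
            seqnames = annotation@genomeId,
            ranges = IRanges::ranges(t), strand = GenomicRanges::strand(t))
        S4Vectors::mcols(gt) <- S4Vectors::DataFrame(
            source = "PhageRecode", type = "tRNA",
            ID = sprintf("%s_trna%03d", annotation@genomeId, seq_along(t)),
            anticodon = mt$anticodon,
            is_suppressor = as.character(mt$is_suppressor),
            suppressed_stop = mt$suppressed_stop)
        feats <- if (length(feats)) suppressWarnings(c(feats, gt)) else gt
    }
    feats
}

#' Write an annotation to GFF3
#'
#' CDS and tRNA features with 1-based inclusive coordinates; CDS rows carry
#' \code{transl_table} and a \code{reassigned_stops} attribute listing the
#' forward-strand positions of internal reassigned stop codons.
#'
#' @param annotation A \linkS4class{PhageAnnotation}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeGff3 <- function(annotation, path) {
    checkBounds(annotation)
    feats <- annotationToGRanges(annotation)
    GenomeInfoDb::seqlengths(feats) <-
        setNames(max(annotation@genomeLength,
                     if (length(feats)) max(GenomicRanges::end(feats)) else 1L),
                 annotation@genomeId)
    rtracklayer::export(feats, path, format = "gff3")
    invisible(path)
}

checkBounds <- function(annotation) {
    o <- orfs(annotation); t <- trnas(annotation)
    wraps <- S4Vectors::mcols(o)$wraps %||% rep(FALSE, length(o))
    bad <- GenomicRanges::start(o) < 1L |
        (GenomicRanges::end(o) > annotation@genomeLength & !wraps)
    if (any(bad)) stop("ORF feature out of genome bounds")
    if (length(t) && (any(GenomicRanges::start(t) < 1L) ||
                      any(GenomicRanges::end(t) > annotation@genomeLength)))
        stop("tRNA feature out of genome bounds")
    invisible(TRUE)
}

#' Read a PhageRecode GFF3 annotation back
#'
#' Parses a GFF3 written by \code{\link{writeGff3}} into a
#' \linkS4class{PhageAnnotation} (coordinates, strands, translation table
#' and reassigned-stop positions round-trip losslessly; proteins are
#' re-derived from the genome when provided).
#'
#' @param path GFF3 path.
#' @param genome Genome (used for id/length and to re-translate proteins);
#'   optional.
#' @return A \linkS4class{PhageAnnotation}.
#' @export
readGff3Annotation <- function(path, genome = NULL) {
    feats <- rtracklayer::import(path, format = "gff3")
    cds <- feats[as.character(feats$type) == "CDS"]
    trn <- feats[as.character(feats$type) == "tRNA"]
    gid <- as.character(GenomeInfoDb::seqnames(feats))[1L] %||% "genome"
    L <- if (!is.null(genome)) nchar(asGenome(genome)$seq)
         else max(GenomicRanges::end(feats), 1L)
    tab <- if (length(cds)) as.integer(cds$transl_table[1L]) else 11L
    reass <- lapply(as.character(cds$reassigned_stops), function(s) {
        if (is.na(s) || !nzchar(s)) integer()
        else as.integer(strsplit(s, ",", fixed = TRUE)[[1L]])
    })
    ogr <- GenomicRanges::GRanges(
        seqnames = gid, ranges = IRanges::ranges(cds),
        strand = GenomicRanges::strand(cds),
        frame = as.integer(cds$frame),
        table_id = tab,
        length_aa = (IRanges::width(cds)) %/% 3L - 1L,
        protein = NA_character_,
        n_reassigned_stops = lengths(reass),
        reassigned_starts = IRanges::IntegerList(reass),
        wraps = GenomicRanges::end(cds) > L)
    tdf <- if (length(trn))
        data.frame(start = GenomicRanges::start(trn),
                   end = GenomicRanges::end(trn),
                   strand = as.character(GenomicRanges::strand(trn)),
                   score = 0L, anticodon = as.character(trn$anticodon),
                   source = "external") else NULL
    new("PhageAnnotation", genomeId = gid, genomeLength = L,
        orfs = sort(ogr, ignore.strand = TRUE), trnas = trnaGRanges(tdf, gid),
        tableId = tab)
}

gbLocation <- function(start, end, strand) {
    loc <- sprintf("%d..%d", start, end)
    if (strand == "-") sprintf("complement(%s)", loc) else loc
}

gbQualifier <- function(name, value, quote = TRUE) {
    v <- if (quote) sprintf("\"%s\"", value) else as.character(value)
    strwrap(sprintf("/%s=%s", name, v), width = 58, exdent = 0) |>
        vapply(function(l) paste0(strrep(" ", 21), l), "")
}

#' Write an annotation as a GenBank flat file
#'
#' Minimal but well-formed GenBank record: LOCUS/DEFINITION headers, CDS
#' features carrying \code{/transl_table} equal to the annotation's table
#' and a \code{/note} listing internal reassigned-stop positions, tRNA
#' features with \code{/note} anticodon, and the ORIGIN sequence block.
#'
#' @param annotation A \linkS4class{PhageAnnotation}.
#' @param genome The genome sequence.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeGenbank <- function(annotation, genome, path) {
    g <- asGenome(genome)
    checkBounds(annotation)
    con <- file(path, "w")
    on.exit(close(con))
    L <- nchar(g$seq)
    topo <- if (identical(g$topology, "circular")) "circular" else "linear"
    wl <- function(...) writeLines(sprintf(...), con)
    wl("LOCUS       %-16s %d bp    DNA     %-8s PHG %s",
       substr(g$id, 1, 16), L, topo, format(Sys.Date(), "%d-%b-%Y"))
    wl("DEFINITION  %s", if (nzchar(g$id)) g$id else "phage genome")
    wl("FEATURES             Location/Qualifiers")
    wl("     source          1..%d", L)
    writeLines(gbQualifier("organism", g$id), con)
    o <- orfs(annotation)
    mo <- S4Vectors::mcols(o)
    for (i in seq_along(o)) {
        wl("     CDS             %s",
           gbLocation(GenomicRanges::start(o)[i],
                      GenomicRanges::end(o)[i],
                      as.character(GenomicRanges::strand(o))[i]))
        writeLines(gbQualifier("locus_tag",
                               sprintf("%s_orf%03d", g$id, i)), con)
        writeLines(gbQualifier("transl_table", mo$table_id[i],
                               quote = FALSE), con)
        rs <- mo$reassigned_starts[[i]]
        if (length(rs))
            writeLines(gbQualifier("note", sprintf(
                "internal reassigned stop codon(s) at %s",
                paste(rs, collapse = ", "))), con)
    }
    t <- trnas(annotation)
    mt <- S4Vectors::mcols(t)
    for (i in seq_along(t)) {
        wl("     tRNA            %s",
           gbLocation(GenomicRanges::start(t)[i],
                      GenomicRanges::end(t)[i],
                      as.character(GenomicRanges::strand(t))[i]))
        writeLines(gbQualifier("note", sprintf(
            "anticodon %s%s", mt$anticodon[i],
            if (isTRUE(mt$is_suppressor[i]))
                sprintf(" (suppressor of %s)", mt$suppressed_stop[i])
            else "")), con)
    }
    wl("ORIGIN")
    sq <- tolower(g$seq)
    for (s in seq(1L, L, by = 60L)) {
        chunk <- substr(sq, s, min(s + 59L, L))
        blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                            pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
        wl("%9d %s", s, paste(blocks, collapse = " "))
    }
    wl("//")
    invisible(path)
}
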