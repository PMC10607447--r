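#' Pipeline configuration
#'
#' Central defaults for the annotation and comparison pipelines; any field
#' can be overridden by name, or loaded from a YAML file. The defaults are
#' the documented study conditions for all reproducibility runs.
#'
#' @param ... Named overrides of the defaults.
#' @param yaml Optional path to a YAML file of overrides (applied first).
#' @return Named list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(..., yaml = NULL) {
    cfg <- list(
        minLengthAa = 30L,
        startCodons = c("ATG", "GTG", "TTG"),
        overlapPolicy = "longest_per_stop",
        minFragmentAa = 15L,
        gMin = 0.02, kMin = 5L,
        gapConvention = "mismatch",
        anchorK = 15L,
        sgSeedLen = 4L, sgXdrop = 20, sgMinScore = 70,
        speciesThreshold = 95, genusThreshold = 70,
        linkage = "single",
        seed = 1L)
    if (!is.null(yaml)) {
        over <- yaml::read_yaml(yaml)
        cfg[names(over)] <- over
    }
    dots <- list(...)
    if (length(dots)) {
        bad <- setdiff(names(dots), names(cfg))
        if (length(bad)) stop("unknown config field(s): ",
                              paste(bad, collapse = ", "))
        cfg[names(dots)] <- dots
    }
    structure(cfg, class = "PipelineConfig")
}

configHash <- function(cfg) {
    s <- paste(deparse(cfg[order(names(unclass(cfg)))]), collapse = "")
    ## small stable polynomial hash, hex
    h <- 5381
    for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
    sprintf("%08x", as.integer(h))
}

writeManifest <- function(outDir, inputs, cfg) {
    jsonlite::write_json(
        list(tool = "PhageRecode",
             version = as.character(packageVersion("PhageRecode")),
             inputs = inputs, config = unclass(cfg),
             config_hash = configHash(cfg),
             date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
        file.path(outDir, "manifest.json"), auto_unbox = TRUE, digits = NA)
}

orfTsv <- function(annotation) {
    o <- orfs(annotation)
    mo <- S4Vectors::mcols(o)
    data.frame(id = sprintf("%s_orf%03d", annotation@genomeId, seq_along(o)),
               start = GenomicRanges::start(o), end = GenomicRanges::end(o),
               strand = as.character(GenomicRanges::strand(o)),
               frame = mo$frame, length_aa = mo$length_aa,
               n_internal_reassigned_stops = mo$n_reassigned_stops)
}

#' Annotate genomes end to end
#'
#' For each genome in the input FASTA: tRNA detection (or external GFF3
#' ingest), recoding analysis over TAG/TGA/TAA, code decision, final
#' re-annotation under the recommended table, and GFF3/GenBank/TSV/JSON
#' outputs plus a run manifest.
#'
#' @param input Path to a FASTA file, or a \code{DNAStringSet}.
#' @param outDir Output directory (created).
#' @param config A \code{\link{pipelineConfig}}.
#' @param trnaGff Optional named list genome id -> external tRNA GFF3 path.
#' @return Invisibly, a named list per genome with \code{report}
#'   (\linkS4class{RecodingReport}), \code{annotation}
#'   (\linkS4class{PhageAnnotation}) and \code{summary}.
#' @export
runAnnotate <- function(input, outDir, config = pipelineConfig(),
                        trnaGff = NULL) {
    genomes <- if (is.character(input)) readGenomes(input) else input
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    results <- list()
    statsAll <- list()
    for (i in seq_along(genomes)) {
        gi <- genomes[i]
        id <- names(genomes)[i]
        tg <- if (!is.null(trnaGff) && !is.null(trnaGff[[id]]))
            ingestExternalTrnas(trnaGff[[id]], gi) else detectTrnas(gi)
        rep <- recodingReport(gi, trnaGr = tg, detect = FALSE,
                              minLengthAa = config$minLengthAa,
                              startCodons = config$startCodons,
                              minFragmentAa = config$minFragmentAa,
                              gMin = config$gMin, kMin = config$kMin)
        v <- verdict(rep)
        code <- geneticCode(v$recommended_table)
        ann <- annotateRecoded(gi, code, tg,
                               minLengthAa = config$minLengthAa,
                               startCodons = config$startCodons,
                               overlapPolicy = config$overlapPolicy)
        writeGff3(ann, file.path(outDir, paste0(id, ".gff3")))
        writeGenbank(ann, gi, file.path(outDir, paste0(id, ".gbk")))
        write.table(orfTsv(ann), file.path(outDir, paste0(id, "_orfs.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        mt <- S4Vectors::mcols(tg)
        write.table(
            data.frame(start = GenomicRanges::start(tg),
                       end = GenomicRanges::end(tg),
                       strand = as.character(GenomicRanges::strand(tg)),
                       anticodon = mt$anticodon,
                       is_suppressor = mt$is_suppressor,
                       suppressed_stop = mt$suppressed_stop,
                       source = mt$source),
            file.path(outDir, paste0(id, "_trnas.tsv")),
            sep = "\t", quote = FALSE, row.names = FALSE)
        st <- recodingStats(rep); st <- cbind(genome = id, st)
        statsAll[[id]] <- st
        sm <- recodedOrfStats(ann)
        jsonlite::write_json(
            list(genome = id, verdict = v, summary = sm,
                 n_trnas = length(tg),
                 n_suppressor_trnas =
                     sum(S4Vectors::mcols(tg)$is_suppressor)),
            file.path(outDir, paste0(id, "_verdict.json")),
            auto_unbox = TRUE, digits = NA)
        results[[id]] <- list(report = rep, annotation = ann, summary = sm)
    }
    write.table(do.call(rbind, statsAll),
                file.path(outDir, "recoding_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeManifest(outDir, if (is.character(input)) input else "in-memory",
                  config)
    invisible(results)
}

#' Compare a genome set end to end
#'
#' Computes NI, SG and intergenomic-similarity matrices, writes them as
#' percent TSVs (one decimal), clusters genomes into putative species and
#' genera, and writes the clustering as JSON plus a run manifest.
#'
#' @inheritParams runAnnotate
#' @return Invisibly, list with the three \linkS4class{SimilarityMatrix}
#'   objects and the \linkS4class{TaxonClustering}.
#' @export
runCompare <- function(input, outDir, config = pipelineConfig()) {
    genomes <- if (is.character(input)) readGenomes(input) else input
    if (length(genomes) < 2L) stop("need at least 2 genomes to compare")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeMat <- function(m, path) {
        pct <- round(100 * similarityValues(m), 1)
        write.table(pct, path, sep = "\t", quote = FALSE, col.names = NA)
    }
    ni <- similarityMatrix(genomes, "NI", k = config$anchorK,
                           gapConvention = config$gapConvention)
    sg <- similarityMatrix(genomes, "SG", seedLen = config$sgSeedLen,
                           xdrop = config$sgXdrop,
                           minScore = config$sgMinScore)
    ig <- similarityMatrix(genomes, "intergenomic_similarity",
                           k = config$anchorK)
    writeMat(ni, file.path(outDir, "ni_matrix.tsv"))
    writeMat(sg, file.path(outDir, "sg_matrix.tsv"))
    writeMat(ig, file.path(outDir, "intergenomic_similarity.tsv"))
    cl <- clusterTaxa(ig, config$speciesThreshold, config$genusThreshold,
                      config$linkage)
    jsonlite::write_json(
        list(species_threshold = cl@speciesThreshold,
             genus_threshold = cl@genusThreshold,
             linkage = cl@linkage,
             species = split(names(speciesClusters(cl)),
                             speciesClusters(cl)),
             genera = split(names(genusClusters(cl)), genusClusters(cl))),
        file.path(outDir, "clusters.json"), auto_unbox = TRUE, digits = NA)
    writeManifest(outDir, if (is.character(input)) input else "in-memory",
                  config)
    invisible(list(ni = ni, sg = sg, intergenomic = ig, clustering = cl))
}
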