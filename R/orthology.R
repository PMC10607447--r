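annotationProteins <- function(annotation) {
    p <- S4Vectors::mcols(orfs(annotation))$protein
    if (is.null(p)) p <- character()
    names(p) <- sprintf("%s_orf%03d", annotation@genomeId, seq_along(p))
    p
}

## identity / coverage of one global protein alignment
alignmentIdCov <- function(pa, lenX, lenY) {
    s1 <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
    s2 <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
    paired <- s1 != "-" & s2 != "-"
    matches <- sum(paired & s1 == s2)
    p <- sum(paired)
    c(identity = if (p) 100 * matches / p else 0,
      coverage = 100 * p / max(lenX, lenY))
}

#' Reciprocal-best-hit orthologs between two annotated genomes
#'
#' All-vs-all global protein alignments (Needleman-Wunsch, affine gaps,
#' BLOSUM62) between the two proteomes; a pair is an ortholog when each
#' protein is the other's highest-scoring hit and identity/coverage pass
#' the thresholds. Proteomes should be the recoded ones (each genome's
#' recommended table): under the standard table recoded genes fragment and
#' orthologs are missed.
#'
#' @param annotA,annotB \linkS4class{PhageAnnotation} objects.
#' @param minIdentity Minimum percent identity over aligned residues.
#' @param minCoverage Minimum percent of the longer protein aligned.
#' @return List of class \code{"OrthologTable"}: \code{genomes},
#'   \code{pairs} (data.frame orf_a, orf_b, identity, coverage, score),
#'   \code{n_shared}.
#' @export
rbhOrthologs <- function(annotA, annotB, minIdentity = 30, minCoverage = 50) {
    pa <- annotationProteins(annotA)
    pb <- annotationProteins(annotB)
    empty <- structure(list(genomes = c(annotA@genomeId, annotB@genomeId),
                            pairs = data.frame(orf_a = character(),
                                               orf_b = character(),
                                               identity = numeric(),
                                               coverage = numeric(),
                                               score = numeric()),
                            n_shared = 0L), class = "OrthologTable")
    if (!length(pa) || !length(pb)) return(empty)
    aset <- Biostrings::AAStringSet(pa)
    bset <- Biostrings::AAStringSet(pb)
    submat <- sgSubMatrix()
    scores <- matrix(-Inf, length(pa), length(pb),
                     dimnames = list(names(pa), names(pb)))
    for (j in seq_along(pb)) {
        al <- Biostrings::pairwiseAlignment(aset, bset[[j]],
                                            substitutionMatrix = submat,
                                            gapOpening = 10, gapExtension = 0.5,
                                            type = "global",
                                            scoreOnly = TRUE)
        scores[, j] <- al
    }
    bestAB <- apply(scores, 1L, which.max)
    bestBA <- apply(scores, 2L, which.max)
    mutual <- which(bestBA[bestAB] == seq_along(pa))
    rows <- list(); k <- 0L
    for (i in mutual) {
        j <- bestAB[i]
        pal <- Biostrings::pairwiseAlignment(aset[[i]], bset[[j]],
                                             substitutionMatrix = submat,
                                             gapOpening = 10,
                                             gapExtension = 0.5,
                                             type = "global")
        ic <- alignmentIdCov(pal, nchar(pa[i]), nchar(pb[j]))
        if (ic["identity"] >= minIdentity && ic["coverage"] >= minCoverage) {
            k <- k + 1L
            rows[[k]] <- data.frame(orf_a = names(pa)[i], orf_b = names(pb)[j],
                                    identity = unname(ic["identity"]),
                                    coverage = unname(ic["coverage"]),
                                    score = scores[i, j])
        }
    }
    if (!k) return(empty)
    out <- empty
    out$pairs <- do.call(rbind, rows)
    out$n_shared <- k
    out
}

#' Core orthologs shared by all genomes in a set
#'
#' Builds a graph whose edges are the RBH pairs of every pairwise table
#' and counts connected components containing exactly one ORF from each
#' genome.
#'
#' @param tables List of \code{OrthologTable}s over one genome set.
#' @return Integer: number of core ortholog groups; attribute
#'   \code{"groups"} holds the member lists.
#' @export
sharedCore <- function(tables) {
    genomes <- unique(unlist(lapply(tables, `[[`, "genomes")))
    if (length(genomes) < 2L) stop("need tables over >= 2 genomes")
    edges <- do.call(rbind, lapply(tables, function(t)
        t$pairs[, c("orf_a", "orf_b")]))
    if (is.null(edges) || !nrow(edges)) {
        out <- 0L; attr(out, "groups") <- list(); return(out)
    }
    ggraph <- igraph::graph_from_data_frame(edges, directed = FALSE)
    comps <- igraph::components(ggraph)
    memb <- split(names(comps$membership), comps$membership)
    orfGenome <- function(ids) sub("_orf[0-9]+$", "", ids)
    core <- Filter(function(ids) {
        gs <- orfGenome(ids)
        length(ids) == length(genomes) && setequal(gs, genomes) &&
            !anyDuplicated(gs)
    }, memb)
    out <- length(core)
    attr(out, "groups") <- unname(core)
    out
}

#' Gene-order conservation between two genomes
#'
#' Kendall rank correlation between the genomic order indices of the
#' orthologs in the two genomes. Strand-aware: when the majority of
#' ortholog pairs lie on opposite strands, the second genome's order is
#' reversed first (an inversion flag is set), so a perfectly collinear
#' inverted genome still scores tau = 1.
#'
#' @param table An \code{OrthologTable} from \code{\link{rbhOrthologs}}.
#' @param annotA,annotB The corresponding annotations.
#' @return List of class \code{"SyntenyScore"}: \code{tau},
#'   \code{adjacency_fraction}, \code{inverted}, \code{n_pairs};
#'   \code{tau} is NA (flagged) with fewer than 2 pairs.
#' @export
syntenyScore <- function(table, annotA, annotB) {
    prs <- table$pairs
    out <- structure(list(genomes = table$genomes, tau = NA_real_,
                          adjacency_fraction = NA_real_, inverted = FALSE,
                          n_pairs = nrow(prs)), class = "SyntenyScore")
    if (nrow(prs) < 2L) return(out)
    ia <- as.integer(sub(".*_orf", "", prs$orf_a))
    ib <- as.integer(sub(".*_orf", "", prs$orf_b))
    sa <- as.character(GenomicRanges::strand(orfs(annotA)))[ia]
    sb <- as.character(GenomicRanges::strand(orfs(annotB)))[ib]
    opposite <- mean(sa != sb) > 0.5
    ra <- rank(GenomicRanges::start(orfs(annotA))[ia])
    rb <- rank(GenomicRanges::start(orfs(annotB))[ib])
    if (opposite) rb <- max(rb) + 1 - rb
    out$inverted <- opposite
    out$tau <- cor(ra, rb, method = "kendall")
    ## adjacency: consecutive orthologs in a that are also consecutive in b
    oa <- order(ra)
    out$adjacency_fraction <- mean(abs(diff(rb[oa])) == 1)
    out
}
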