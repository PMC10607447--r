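## Run expr with a private, seeded RNG stream; restores the caller's state.
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
             sample.kind = "Rejection")
    force(expr)
}

#' Specification for a synthetic phage genome
#'
#' Defaults emulate the gene-dense organisation of tailed-phage genomes in
#' which roughly a quarter of genes carry internal amber (TAG) codons that
#' are glutamine sense codons under the phage's code, with a small number
#' of amber-suppressor tRNA genes (anticodon CTA) embedded between genes.
#'
#' @param nGenes Number of protein-coding genes.
#' @param geneLengthAa (min, max) protein length, drawn uniformly.
#' @param intergenicLength (min, max) intergenic spacer length in bp.
#' @param gcContent Target GC fraction.
#' @param recodedFraction Fraction of genes carrying internal TAG codons.
#' @param ambersPerGene (min, max) internal TAG codons per recoded gene.
#' @param nSuppressorTrnas Number of suppressor (anticodon CTA) tRNA genes.
#' @param strandFlipProb Probability a gene is placed on the minus strand.
#' @param topology "linear" or "circular".
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A validated list of class \code{"SyntheticSpec"}.
#' @export
syntheticSpec <- function(nGenes = 20L, geneLengthAa = c(100L, 400L),
                          intergenicLength = c(20L, 120L),
                          gcContent = 0.445, recodedFraction = 0.28,
                          ambersPerGene = c(1L, 4L),
                          nSuppressorTrnas = 3L, strandFlipProb = 0.3,
                          topology = c("linear", "circular"), seed = 1L) {
    topology <- match.arg(topology)
    stopifnot(nGenes >= 1L, gcContent > 0, gcContent < 1,
              recodedFraction >= 0, recodedFraction <= 1,
              strandFlipProb >= 0, strandFlipProb <= 1,
              length(geneLengthAa) == 2L, geneLengthAa[1L] >= 40L,
              geneLengthAa[1L] <= geneLengthAa[2L],
              length(ambersPerGene) == 2L, ambersPerGene[1L] >= 1L,
              ambersPerGene[1L] <= ambersPerGene[2L],
              nSuppressorTrnas >= 0L)
    structure(list(nGenes = as.integer(nGenes),
                   geneLengthAa = as.integer(geneLengthAa),
                   intergenicLength = as.integer(intergenicLength),
                   gcContent = gcContent,
                   recodedFraction = recodedFraction,
                   ambersPerGene = as.integer(ambersPerGene),
                   nSuppressorTrnas = as.integer(nSuppressorTrnas),
                   strandFlipProb = strandFlipProb,
                   topology = topology, seed = as.integer(seed)),
              class = "SyntheticSpec")
}

SENSE_CODONS <- local({
    b <- c("A", "C", "G", "T")
    all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
    sort(setdiff(all64, c("TAA", "TAG", "TGA")))
})

## GC-consistent codon weights over the 61 sense codons.
codonWeights <- function(gc) {
    pb <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    w <- vapply(SENSE_CODONS, function(cd) {
        prod(pb[strsplit(cd, "")[[1L]]])
    }, 0)
    w / sum(w)
}

## Synthetic cloverleaf tRNA gene (canonical numbering, 76 nt) carrying
## the given anticodon. The same structural layout the detector scans for.
trnaTemplate <- function(anticodon) {
    paste0("GGGCCCG", "CA", "GCTC", "AGTTGGTA", "GAGC", "G",
           "CTGGA", "CT", anticodon, "AA", "TCCAG",
           "GTTAG", "GGTCG", "TTCGAAT", "CGACC", "CGGGCCC", "A", "CCA")
}

randomDna <- function(n, gc) {
    if (n <= 0L) return("")
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
}

## Sample amber codon indices (1-based codon number within the protein)
## with clearance from both ends and between ambers.
sampleAmberPositions <- function(lenAa, k, minSep = 20L) {
    lo <- minSep + 1L
    hi <- lenAa - minSep
    for (. in 1:200) {
        pos <- sort(sample(lo:hi, k))
        if (k == 1L || min(diff(pos)) >= minSep) return(pos)
    }
    ## dense fallback: evenly spaced
    as.integer(round(seq(lo, hi, length.out = k)))
}

#' Generate a synthetic phage genome with ground truth
#'
#' Genes are drawn codon-wise from a GC-consistent distribution over the 61
#' sense codons (so no in-frame stop can occur by accident), open with ATG
#' and close with TAA. Recoded genes carry internal TAG codons at designed
#' positions. Suppressor tRNA genes are inserted between genes as canonical
#' cloverleaf sequences with anticodon CTA. Fully deterministic given
#' \code{spec$seed}.
#'
#' @param spec A \code{\link{syntheticSpec}}.
#' @return List with \code{genome} (one-record \code{DNAStringSet}) and
#'   \code{truth}: \code{genes} data.frame (start/end/strand/length_aa/
#'   recoded/n_ambers), \code{ambers} data.frame (gene, codon_index, start
#'   = forward 1-based leftmost base of each designed TAG), \code{trnas}
#'   data.frame, \code{mutations} (empty log).
#' @export
generateGenome <- function(spec) {
    stopifnot(inherits(spec, "SyntheticSpec"))
    withSeed(spec$seed, {
        n <- spec$nGenes
        w <- codonWeights(spec$gcContent)
        lens <- sample(spec$geneLengthAa[1L]:spec$geneLengthAa[2L], n,
                       replace = TRUE)
        nRec <- as.integer(round(spec$recodedFraction * n))
        recoded <- sort(sample.int(n, nRec))
        strands <- ifelse(runif(n) < spec$strandFlipProb, "-", "+")
        genes <- vector("list", n)
        amberIdx <- vector("list", n)
        for (i in seq_len(n)) {
            codons <- sample(SENSE_CODONS, lens[i] - 1L, replace = TRUE,
                             prob = w)
            codons <- c("ATG", codons)   # protein codons, length lens[i]
            if (i %in% recoded) {
                k <- sample(spec$ambersPerGene[1L]:spec$ambersPerGene[2L], 1L)
                pos <- sampleAmberPositions(lens[i], k)
                codons[pos] <- "TAG"
                amberIdx[[i]] <- pos
            } else amberIdx[[i]] <- integer()
            genes[[i]] <- paste(c(codons, "TAA"), collapse = "")
        }
        ## interleave: intergenic spacers, genes, tRNA insertions
        nT <- spec$nSuppressorTrnas
        trnaSlots <- if (nT > 0L) sort(sample.int(n + 1L, nT, replace = TRUE))
                     else integer()
        parts <- character(0)
        type <- character(0)      # "ig", gene index, or "trna<j>"
        addIg <- function() {
            len <- sample(spec$intergenicLength[1L]:spec$intergenicLength[2L], 1L)
            parts <<- c(parts, randomDna(len, spec$gcContent))
            type <<- c(type, "ig")
        }
        trnaStrands <- character(nT); tj <- 0L
        for (slot in seq_len(n + 1L)) {
            addIg()
            for (. in which(trnaSlots == slot)) {
                tj <- tj + 1L
                st <- if (runif(1) < 0.5) "-" else "+"
                trnaStrands[tj] <- st
                tpl <- trnaTemplate("CTA")
                parts <- c(parts, if (st == "-") revComp(tpl) else tpl)
                type <- c(type, paste0("trna", tj))
                addIg()
            }
            if (slot <= n) {
                ## in-frame guard stop on the gene's 5' side: real genes sit
                ## in stop-bounded context, so the longest-ORF start rule
                ## recovers the annotated start instead of running upstream
                ## through the spacer
                parts <- c(parts,
                           if (strands[slot] == "-")
                               paste0(revComp(genes[[slot]]), "TTA")
                           else paste0("TAA", genes[[slot]]))
                type <- c(type, as.character(slot))
            }
        }
        seqs <- paste(parts, collapse = "")
        offs <- cumsum(c(0L, nchar(parts)))   # 0-based part offsets
        ## truth tables
        ## part includes the 3-nt guard stop; the gene proper excludes it
        geneRow <- function(i) {
            p <- which(type == as.character(i))
            if (strands[i] == "-")
                c(start = offs[p] + 1L, end = offs[p] + nchar(parts[p]) - 3L)
            else
                c(start = offs[p] + 4L, end = offs[p] + nchar(parts[p]))
        }
        gpos <- t(vapply(seq_len(n), geneRow, c(start = 0L, end = 0L)))
        truthGenes <- data.frame(gene = seq_len(n), start = gpos[, 1L],
                                 end = gpos[, 2L], strand = strands,
                                 length_aa = lens,
                                 recoded = seq_len(n) %in% recoded,
                                 n_ambers = lengths(amberIdx))
        ambers <- do.call(rbind, lapply(seq_len(n), function(i) {
            pos <- amberIdx[[i]]
            if (!length(pos)) return(NULL)
            Lg <- gpos[i, 2L] - gpos[i, 1L] + 1L
            start <- if (strands[i] == "+") gpos[i, 1L] + 3L * (pos - 1L)
                     else gpos[i, 1L] + (Lg - 3L * pos)
            data.frame(gene = i, codon_index = pos, start = sort(start))
        }))
        if (is.null(ambers))
            ambers <- data.frame(gene = integer(), codon_index = integer(),
                                 start = integer())
        truthTrnas <- if (nT > 0L) {
            p <- match(paste0("trna", seq_len(nT)), type)
            data.frame(trna = seq_len(nT), start = offs[p] + 1L,
                       end = offs[p] + nchar(parts[p]),
                       strand = trnaStrands, anticodon = "CTA")
        } else data.frame(trna = integer(), start = integer(),
                          end = integer(), strand = character(),
                          anticodon = character())
        genome <- Biostrings::DNAStringSet(seqs)
        names(genome) <- sprintf("synthetic_seed%d", spec$seed)
        S4Vectors::mcols(genome) <- S4Vectors::DataFrame(
            topology = spec$topology, description = "synthetic phage genome")
        list(genome = genome,
             truth = list(genes = truthGenes, ambers = ambers,
                          trnas = truthTrnas,
                          mutations = data.frame(type = character(),
                                                 pos = integer(),
                                                 ref = character(),
                                                 alt = character(),
                                                 length = integer()),
                          spec = spec))
    })
}

## Which proposed substitutions survive purifying selection: inside truth
## genes, a substitution must not create an in-frame stop on the coding
## strand nor hit the start codon, the terminal stop, or a designed amber.
## Substitutions are vetted sequentially against the partially mutated
## sequence, so two hits in one codon cannot jointly create a stop.
subAllowed <- function(chars, subAt, alt, truth) {
    genes <- truth$genes
    amberStarts <- if (!is.null(truth$ambers)) truth$ambers$start else integer()
    ok <- rep(TRUE, length(subAt))
    gi <- findInterval(subAt, genes$start)
    inGene <- gi >= 1L & subAt <= genes$end[pmax(gi, 1L)]
    amberBases <- unlist(lapply(amberStarts, function(s) s:(s + 2L)))
    work <- chars
    for (q in seq_along(subAt)) {
        p <- subAt[q]
        if (!inGene[q]) { work[p] <- alt[q]; next }
        i <- gi[q]
        if (p %in% amberBases) { ok[q] <- FALSE; next }
        if (genes$strand[i] == "+") {
            off <- p - genes$start[i]
            c0 <- genes$start[i] + 3L * (off %/% 3L)
        } else {
            off <- genes$end[i] - p
            c0 <- genes$end[i] - 3L * (off %/% 3L) - 2L
        }
        ## start codon and terminal stop are invariant on either strand
        if (c0 == genes$start[i] || c0 + 2L == genes$end[i]) {
            ok[q] <- FALSE; next
        }
        cod <- work[c0:(c0 + 2L)]
        cod[p - c0 + 1L] <- alt[q]
        cods <- paste(cod, collapse = "")
        if (genes$strand[i] == "-") cods <- revComp(cods)
        if (cods %in% TABLE11_STOPS) { ok[q] <- FALSE; next }
        work[p] <- alt[q]
    }
    ok
}

#' Mutate a genome with a recorded event log
#'
#' Applies per-site substitutions at \code{subRate} (uniform over the three
#' alternative bases) and indels of length 1-6 at \code{indelRate}. Every
#' event is logged with its position in the *original* coordinate system,
#' so the realized substitution fraction is an exact oracle for alignment
#' identity on substitution-only runs.
#'
#' @param genome One-record \code{DNAStringSet} (or string).
#' @param truth Truth list to carry the log (may be NULL).
#' @param subRate Per-site substitution probability, in [0, 0.5].
#' @param indelRate Per-site indel initiation probability, in [0, 0.5].
#' @param seed Integer seed.
#' @param preserveOrfs Emulate purifying selection on reading frames:
#'   substitutions that would create an in-frame stop codon inside a truth
#'   gene, or touch a gene's start/stop codon or a designed amber codon,
#'   are rejected. Requires \code{truth$genes} (and uses
#'   \code{truth$ambers}); incompatible with \code{indelRate > 0}.
#' @param id Name for the mutated record (default: original id suffixed
#'   with \code{_mut<seed>}).
#' @return List with \code{genome} (mutated, id suffixed \code{_mut}),
#'   \code{truth} (with \code{mutations} log appended) and
#'   \code{realizedSubFraction}.
#' @export
mutateGenome <- function(genome, truth = NULL, subRate = 0.05,
                         indelRate = 0, seed = 1L, preserveOrfs = FALSE,
                         id = NULL) {
    stopifnot(subRate >= 0, subRate <= 0.5, indelRate >= 0, indelRate <= 0.5)
    if (preserveOrfs && (is.null(truth) || is.null(truth$genes)))
        stop("preserveOrfs requires truth$genes")
    if (preserveOrfs && indelRate > 0)
        stop("preserveOrfs supports substitutions only")
    g <- asGenome(genome)
    withSeed(seed, {
        chars <- strsplit(g$seq, "", fixed = TRUE)[[1L]]
        L <- length(chars)
        subAt <- which(runif(L) < subRate)
        ref <- chars[subAt]
        alt <- vapply(ref, function(b) sample(setdiff(c("A","C","G","T"), b), 1L),
                      "")
        if (preserveOrfs && length(subAt)) {
            ok <- subAllowed(chars, subAt, alt, truth)
            subAt <- subAt[ok]; ref <- ref[ok]; alt <- alt[ok]
        }
        chars[subAt] <- alt
        log <- data.frame(type = rep("sub", length(subAt)), pos = subAt,
                          ref = ref, alt = unname(alt),
                          length = rep(1L, length(subAt)))
        if (indelRate > 0) {
            idAt <- which(runif(L) < indelRate)
            idAt <- idAt[!idAt %in% subAt]
            if (length(idAt)) {
                lens <- sample.int(6L, length(idAt), replace = TRUE)
                isIns <- runif(length(idAt)) < 0.5
                ## apply right-to-left so earlier positions stay valid
                ord <- order(idAt, decreasing = TRUE)
                pieces <- as.list(chars)
                for (k in ord) {
                    p <- idAt[k]
                    if (isIns[k]) {
                        ins <- sample(c("A","C","G","T"), lens[k], replace = TRUE)
                        pieces[[p]] <- c(pieces[[p]], ins)
                    } else {
                        del <- p:min(L, p + lens[k] - 1L)
                        for (d in del) pieces[[d]] <- character()
                    }
                }
                chars <- unlist(pieces)
                log <- rbind(log, data.frame(
                    type = ifelse(isIns, "ins", "del"), pos = idAt,
                    ref = "", alt = "", length = lens))
                log <- log[order(log$pos), , drop = FALSE]
            }
        }
        seqs <- paste(chars, collapse = "")
        out <- Biostrings::DNAStringSet(seqs)
        names(out) <- if (is.null(id)) sprintf("%s_mut%d", g$id, seed) else id
        S4Vectors::mcols(out) <- S4Vectors::DataFrame(
            topology = g$topology, description = "mutated copy")
        if (is.null(truth))
            truth <- list(mutations = log[0, ])
        truth$mutations <- rbind(truth$mutations, log)
        list(genome = out, truth = truth,
             realizedSubFraction = length(subAt) / L)
    })
}
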