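test_that("a constructed single-gene genome yields exactly one forward ORF", {
    gene <- makeGene(33, seed = 2)         # ATG + 32 sense codons + TAA
    ## stop-bounded context in the gene frame; flanks carry no long junk
    genome <- paste0("TAATAATAATAA", gene, "TAATAATAATAA")
    o <- findOrfs(genome, geneticCode(11), minLengthAa = 30)
    fw <- o[as.character(GenomicRanges::strand(o)) == "+"]
    expect_identical(length(fw), 1L)
    expect_identical(S4Vectors::mcols(fw)$length_aa, 33L)
    expect_identical(GenomicRanges::start(fw), 13L)
    expect_identical(GenomicRanges::end(fw), 13L + 34L * 3L - 1L)
    ## no TAG anywhere in the gene frame: table 15 calls agree (only the
    ## table id column differs by construction)
    o15 <- findOrfs(genome, geneticCode(15), minLengthAa = 30)
    dropTab <- function(gr) { d <- as.data.frame(gr); d$table_id <- NULL; d }
    expect_identical(dropTab(o), dropTab(o15))
})

test_that("an in-frame TAG truncates under table 11 and is read through under 15", {
    gene <- makeGene(100, ambersAt = 50, seed = 3)
    genome <- paste0("TAATAATAA", gene, "TAATAATAA")
    o15 <- findOrfs(genome, geneticCode(15), minLengthAa = 30)
    o15 <- o15[as.character(GenomicRanges::strand(o15)) == "+"]
    expect_identical(length(o15), 1L)
    expect_identical(S4Vectors::mcols(o15)$length_aa, 100L)
    expect_identical(S4Vectors::mcols(o15)$n_reassigned_stops, 1L)
    ## the recorded position is the TAG codon's leftmost base
    pos <- S4Vectors::mcols(o15)$reassigned_starts[[1]]
    expect_identical(substr(genome, pos, pos + 2), "TAG")
    ## translation renders the amber as Q, never as *
    expect_false(grepl("*", S4Vectors::mcols(o15)$protein, fixed = TRUE))
    expect_identical(substr(S4Vectors::mcols(o15)$protein, 50, 50), "Q")

    o11 <- findOrfs(genome, geneticCode(11), minLengthAa = 30)
    o11 <- o11[as.character(GenomicRanges::strand(o11)) == "+"]
    expect_true(all(S4Vectors::mcols(o11)$length_aa < 100L))
    expect_true(all(S4Vectors::mcols(o11)$n_reassigned_stops == 0L))
})

test_that("reported ORFs never contain an internal stop in their translation", {
    for (s in 1:4) {
        g <- generateGenome(syntheticSpec(nGenes = 10, recodedFraction = 0.3,
                                          seed = s))
        for (tab in c(11, 15)) {
            o <- findOrfs(g$genome, geneticCode(tab))
            expect_false(any(grepl("*", S4Vectors::mcols(o)$protein,
                                   fixed = TRUE)),
                         info = sprintf("seed %d table %d", s, tab))
        }
    }
})

test_that("ORF calls are invariant under reverse complement up to reflection", {
    for (s in 1:3) {
        g <- generateGenome(syntheticSpec(nGenes = 6, seed = s))
        seqs <- as.character(g$genome[[1]])
        L <- nchar(seqs)
        o1 <- findOrfs(seqs, geneticCode(11))
        o2 <- findOrfs(revComp(seqs), geneticCode(11))
        k1 <- sort(sprintf("%d:%d", GenomicRanges::start(o1),
                           GenomicRanges::end(o1)))
        k2 <- sort(sprintf("%d:%d", L - GenomicRanges::end(o2) + 1L,
                           L - GenomicRanges::start(o2) + 1L))
        expect_identical(k1, k2, info = paste("seed", s))
    }
})

test_that("genomes with no TAG give identical calls under tables 11 and 15", {
    ## codons over {A,C,G} (with care at junctions) form no TAG and no CTA,
    ## so neither strand carries a TAG codon in any frame
    set.seed(5)
    mk <- function() paste(c("ATG",
                             sample(c("GCA", "CAG", "GGA", "ACC", "AAC",
                                      "CCG"), 60, TRUE),
                             "GCA", "TAA"), collapse = "")
    genome <- paste0("TAA", mk(), "TAA", mk(), "TAA", mk(), "GG")
    expect_false(grepl("TAG", genome))
    expect_false(grepl("CTA", genome))
    o11 <- findOrfs(genome, geneticCode(11))
    o15 <- findOrfs(genome, geneticCode(15))
    dropTab <- function(gr) { d <- as.data.frame(gr); d$table_id <- NULL; d }
    expect_identical(dropTab(o11), dropTab(o15))
    expect_true(all(S4Vectors::mcols(o15)$n_reassigned_stops == 0L))
})

test_that("codingFraction implements union semantics and input checks", {
    empty <- GenomicRanges::GRanges()
    expect_identical(codingFraction(empty, 1000L), 0)
    half <- GenomicRanges::GRanges("g", IRanges::IRanges(1, 500))
    expect_equal(codingFraction(half, 1000L), 0.5)
    two <- GenomicRanges::GRanges("g", IRanges::IRanges(c(1, 1), c(500, 500)),
                                  c("+", "-"))
    expect_equal(codingFraction(two, 1000L), 0.5)
    expect_error(codingFraction(half, 0L), "positive")
})

test_that("origin-spanning genes are recovered on circular genomes only", {
    gene <- makeGene(60, seed = 1)
    lin <- paste0("TAA", gene, "TTATTATTA", "TAATAATAA")
    L <- nchar(lin)
    rot <- paste0(substr(lin, 101, L), substr(lin, 1, 100))
    g <- Biostrings::DNAStringSet(rot); names(g) <- "c1"
    S4Vectors::mcols(g) <- S4Vectors::DataFrame(topology = "circular",
                                                description = "")
    o <- findOrfs(g, geneticCode(11), minLengthAa = 55)
    fw <- o[as.character(GenomicRanges::strand(o)) == "+"]
    expect_identical(S4Vectors::mcols(fw)$length_aa, 60L)
    expect_true(all(S4Vectors::mcols(fw)$wraps))
    expect_true(all(GenomicRanges::end(fw) > L))
    S4Vectors::mcols(g)$topology <- "linear"
    o2 <- findOrfs(g, geneticCode(11), minLengthAa = 55)
    expect_identical(length(o2[as.character(GenomicRanges::strand(o2)) == "+"]), 0L)
})

test_that("caller parameter bounds are enforced", {
    expect_error(findOrfs("ATGAAATAA", geneticCode(11), minLengthAa = 5),
                 ">= 10")
    expect_identical(length(findOrfs("ATGTAA", geneticCode(11))), 0L)
})
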