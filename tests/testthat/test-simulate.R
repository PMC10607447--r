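test_that("generator truth is exactly consistent with the emitted sequence", {
    spec <- syntheticSpec(nGenes = 20, recodedFraction = 0.3,
                          nSuppressorTrnas = 3L, seed = 1)
    g <- generateGenome(spec)
    seqs <- as.character(g$genome[[1]])
    expect_identical(sum(g$truth$genes$recoded), 6L)   # round(0.3 * 20)
    ## every designed amber re-derivable by scanning
    for (i in seq_len(nrow(g$truth$ambers))) {
        a <- g$truth$ambers[i, ]
        tri <- substr(seqs, a$start, a$start + 2L)
        st <- g$truth$genes$strand[a$gene]
        expect_identical(if (st == "-") revComp(tri) else tri, "TAG",
                         info = paste("amber", i))
    }
    ## genes open with ATG and close with TAA on their coding strand
    for (i in seq_len(nrow(g$truth$genes))) {
        gn <- g$truth$genes[i, ]
        gs <- substr(seqs, gn$start, gn$end)
        if (gn$strand == "-") gs <- revComp(gs)
        expect_identical(substr(gs, 1, 3), "ATG")
        expect_identical(substr(gs, nchar(gs) - 2, nchar(gs)), "TAA")
        ## no in-frame stop beyond designed ambers and the terminal TAA
        prot <- translateCDS(gs, geneticCode(15))
        expect_identical(substr(prot, nchar(prot), nchar(prot)), "*")
        expect_false(grepl("\\*", substr(prot, 1, nchar(prot) - 1)))
        codons <- substring(gs, seq(1, nchar(gs) - 2, 3),
                            seq(3, nchar(gs), 3))
        expect_identical(sum(codons == "TAG"), gn$n_ambers)
    }
    ## tRNA loci carry the designed anticodon on the right strand
    for (i in seq_len(nrow(g$truth$trnas))) {
        t <- g$truth$trnas[i, ]
        ts <- substr(seqs, t$start, t$end)
        if (t$strand == "-") ts <- revComp(ts)
        expect_identical(substr(ts, 34, 36), "CTA")
    }
})

test_that("generation is deterministic and leaves no stray RNG state", {
    spec <- syntheticSpec(nGenes = 10, recodedFraction = 0.2, seed = 42)
    s1 <- as.character(generateGenome(spec)$genome[[1]])
    set.seed(999)   # generator must not be influenced by ambient state
    s2 <- as.character(generateGenome(spec)$genome[[1]])
    expect_identical(s1, s2)
    g <- generateGenome(spec)
    m1 <- mutateGenome(g$genome, subRate = 0.05, indelRate = 0.002, seed = 3)
    m2 <- mutateGenome(g$genome, subRate = 0.05, indelRate = 0.002, seed = 3)
    expect_identical(as.character(m1$genome[[1]]), as.character(m2$genome[[1]]))
    expect_identical(m1$truth$mutations, m2$truth$mutations)
})

test_that("realized GC content tracks the target within two points", {
    for (s in 1:5) {
        g <- generateGenome(syntheticSpec(nGenes = 50, gcContent = 0.445,
                                          seed = 500 + s))
        chars <- strsplit(as.character(g$genome[[1]]), "")[[1]]
        gc <- mean(chars %in% c("G", "C"))
        expect_lt(abs(gc - 0.445), 0.02, label = paste("seed", 500 + s))
    }
})

test_that("the mutation log is an exact oracle for the realized changes", {
    g <- generateGenome(syntheticSpec(nGenes = 8, seed = 8))
    a <- as.character(g$genome[[1]])
    m0 <- mutateGenome(a, subRate = 0, indelRate = 0, seed = 1)
    expect_identical(as.character(m0$genome[[1]]), a)
    expect_identical(nrow(m0$truth$mutations), 0L)
    m <- mutateGenome(a, subRate = 0.05, seed = 2)
    log <- m$truth$mutations
    expect_identical(m$realizedSubFraction, nrow(log) / nchar(a))
    b <- strsplit(as.character(m$genome[[1]]), "")[[1]]
    ao <- strsplit(a, "")[[1]]
    expect_identical(which(ao != b), log$pos)
    expect_identical(b[log$pos], log$alt)
    ## two rounds of 5% compose to roughly 1 - 0.95^2 realized distance
    m2 <- mutateGenome(m$genome, subRate = 0.05, seed = 3)
    diff2 <- mean(strsplit(as.character(m2$genome[[1]]), "")[[1]] != ao)
    expect_lt(abs(diff2 - (1 - (1 - m$realizedSubFraction) *
                           (1 - m2$realizedSubFraction) -
                           ## back-mutations: two hits can restore the base
                           0)), 0.02)
})

test_that("ORF-preserving mutation never breaks a truth gene", {
    g <- generateGenome(syntheticSpec(nGenes = 12, recodedFraction = 0.25,
                                      seed = 55))
    m <- mutateGenome(g$genome, g$truth, subRate = 0.08, seed = 9,
                      preserveOrfs = TRUE)
    seqs <- as.character(m$genome[[1]])
    for (i in seq_len(nrow(g$truth$genes))) {
        gn <- g$truth$genes[i, ]
        gs <- substr(seqs, gn$start, gn$end)
        if (gn$strand == "-") gs <- revComp(gs)
        prot <- translateCDS(gs, geneticCode(15))
        expect_false(grepl("\\*", substr(prot, 1, nchar(prot) - 1)),
                     info = paste("gene", i))
        expect_identical(substr(gs, 1, 3), "ATG")
    }
    ## designed ambers are untouched
    for (i in seq_len(nrow(g$truth$ambers))) {
        a <- g$truth$ambers[i, ]
        tri <- substr(seqs, a$start, a$start + 2L)
        st <- g$truth$genes$strand[a$gene]
        expect_identical(if (st == "-") revComp(tri) else tri, "TAG")
    }
})

test_that("spec validation rejects degenerate settings", {
    expect_error(syntheticSpec(nGenes = 0))
    expect_error(syntheticSpec(recodedFraction = 1.2))
    expect_error(syntheticSpec(geneLengthAa = c(400, 100)))
    expect_error(mutateGenome("ACGT", subRate = 0.9))
    expect_error(mutateGenome("ACGT", subRate = 0.1, preserveOrfs = TRUE),
                 "truth")
})
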