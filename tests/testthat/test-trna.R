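test_that("suppressor classification is consistent with reverse-complement arithmetic", {
    for (anti in allCodons()) {
        cls <- classifySuppressor(anti)
        expect_identical(cls$decoded_codon, revComp(anti), info = anti)
        expect_identical(cls$is_suppressor,
                         cls$decoded_codon %in% c("TAG", "TGA", "TAA"),
                         info = anti)
    }
    expect_identical(classifySuppressor("CTA")$suppressed_stop, "TAG")
    expect_identical(classifySuppressor("TCA")$suppressed_stop, "TGA")
    expect_identical(classifySuppressor("TTA")$suppressed_stop, "TAA")
    expect_identical(classifySuppressor("CTG")$suppressed_stop, "none")
    expect_error(classifySuppressor("CUN"), "3-nt")
})

test_that("a canonical natural tRNA is detected with its anticodon", {
    ## yeast phenylalanine tRNA, canonical 76-nt cloverleaf (DNA alphabet)
    phe <- paste0("GCGGATTTAGCTCAGTTGGGAGAGCGCCAGACTGAAGATCTGGAGGTCCTGTGT",
                  "TCGATCCACAGAATTCGCACCA")
    genome <- paste0(randomDna(300, 91), phe, randomDna(300, 92))
    tr <- detectTrnas(genome)
    expect_identical(length(tr), 1L)
    expect_identical(S4Vectors::mcols(tr)$anticodon, "GAA")
    expect_false(S4Vectors::mcols(tr)$is_suppressor)
    ## the same gene with anticodon CTA becomes an amber suppressor
    pheSup <- paste0(substr(phe, 1, 33), "CTA", substr(phe, 37, nchar(phe)))
    tr2 <- detectTrnas(paste0(randomDna(300, 91), pheSup, randomDna(300, 92)))
    expect_identical(S4Vectors::mcols(tr2)$anticodon, "CTA")
    expect_true(S4Vectors::mcols(tr2)$is_suppressor)
    expect_identical(S4Vectors::mcols(tr2)$suppressed_stop, "TAG")
})

test_that("all simulated suppressor tRNAs are recovered on both strands", {
    for (s in 1:5) {
        g <- generateGenome(syntheticSpec(nGenes = 10, nSuppressorTrnas = 3L,
                                          seed = 70 + s))
        tr <- detectTrnas(g$genome)
        sup <- tr[S4Vectors::mcols(tr)$is_suppressor]
        expect_identical(length(sup), 3L, info = paste("seed", 70 + s))
        expect_true(all(S4Vectors::mcols(sup)$suppressed_stop == "TAG"))
        ## positions match the truth loci
        for (i in seq_len(nrow(g$truth$trnas)))
            expect_true(any(abs(GenomicRanges::start(sup) -
                                g$truth$trnas$start[i]) <= 5L))
        expect_identical(suppressorSupport(tr, "TAG"), 3L)
    }
})

test_that("detection is strand-symmetric up to coordinate reflection", {
    g <- generateGenome(syntheticSpec(nGenes = 8, nSuppressorTrnas = 2L,
                                      seed = 81))
    seqs <- as.character(g$genome[[1]])
    L <- nchar(seqs)
    t1 <- detectTrnas(seqs)
    t2 <- detectTrnas(revComp(seqs))
    k1 <- sort(sprintf("%d:%d", GenomicRanges::start(t1),
                       GenomicRanges::end(t1)))
    k2 <- sort(sprintf("%d:%d", L - GenomicRanges::end(t2) + 1L,
                       L - GenomicRanges::start(t2) + 1L))
    expect_identical(k1, k2)
})

test_that("the empirical false-positive rate on random sequence is near zero", {
    hits <- vapply(1:40, function(s)
        length(detectTrnas(randomDna(10000, 500 + s))), 0L)
    expect_lte(sum(hits), 3L)   # measured null: ~0.01 detections per 10 kb
})

test_that("external GFF3 tRNA calls are ingested and classified identically", {
    g <- generateGenome(syntheticSpec(nGenes = 6, nSuppressorTrnas = 0L,
                                      seed = 95))
    seqs <- as.character(g$genome[[1]])
    gff <- tempfile(fileext = ".gff3")
    writeLines(c(
        "##gff-version 3",
        sprintf("%s\ttRNAscan-SE\ttRNA\t101\t176\t.\t+\t.\tID=t1;anticodon=CTA",
                names(g$genome)),
        sprintf("%s\ttRNAscan-SE\ttRNA\t301\t376\t.\t-\t.\tID=t2;anticodon=CTG",
                names(g$genome)),
        sprintf("%s\ttRNAscan-SE\ttRNA\t501\t576\t.\t+\t.\tID=t3",
                names(g$genome))), gff)
    expect_warning(tr <- ingestExternalTrnas(gff, g$genome), "skipped")
    expect_identical(length(tr), 2L)
    expect_identical(S4Vectors::mcols(tr)$source, c("external", "external"))
    expect_identical(S4Vectors::mcols(tr)$is_suppressor, c(TRUE, FALSE))
    expect_identical(S4Vectors::mcols(tr)$suppressed_stop[1], "TAG")
    expect_identical(suppressorSupport(tr, "TAG"), 1L)

    ## minus-strand anticodon derived from its genomic position
    gff2 <- tempfile(fileext = ".gff3")
    pos <- 201L
    tri <- substr(seqs, pos, pos + 2L)
    writeLines(c(
        "##gff-version 3",
        sprintf("%s\ttRNAscan-SE\ttRNA\t180\t255\t.\t-\t.\tID=t1;anticodon_start=%d",
                names(g$genome), pos)), gff2)
    tr2 <- ingestExternalTrnas(gff2, g$genome)
    expect_identical(S4Vectors::mcols(tr2)$anticodon, revComp(tri))

    ## bounds violation errors; empty file yields an empty set
    gff3 <- tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3",
                 sprintf("%s\tx\ttRNA\t1\t99999999\t.\t+\t.\tID=t;anticodon=CTA",
                         names(g$genome))), gff3)
    expect_error(ingestExternalTrnas(gff3, g$genome), "bounds")
    writeLines("##gff-version 3", gff3)
    expect_identical(length(ingestExternalTrnas(gff3, g$genome)), 0L)
})
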