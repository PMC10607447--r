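test_that("a single internal TAG yields one interruption candidate with exact join", {
    gene <- makeGene(99, ambersAt = 50, seed = 11)
    genome <- paste0("TAATAATAATAATAA", gene, "TAATAATAATAATAA")
    cand <- findInterruptions(genome, "TAG")
    fw <- cand[cand$strand == "+", ]
    expect_identical(nrow(fw), 1L)
    expect_identical(fw$n_joining_stops, 1L)
    expect_identical(fw$up_len_aa, 49L)
    expect_identical(fw$down_len_aa, 49L)
    expect_identical(fw$joined_length_aa, 99L)
    ## interruption by a different stop type is not a TAG candidate
    geneTga <- gsub("TAG", "TGA", gene, fixed = TRUE)
    genome2 <- paste0("TAATAATAATAATAA", geneTga, "TAATAATAATAATAA")
    cand2 <- findInterruptions(genome2, "TAG")
    expect_identical(nrow(cand2[cand2$strand == "+", ]), 0L)
    expect_identical(nrow(findInterruptions(genome2, "TGA")[
        findInterruptions(genome2, "TGA")$strand == "+", ]), 1L)
})

test_that("chained ambers join transitively across all fragments", {
    gene <- makeGene(90, ambersAt = c(30, 60), seed = 12)
    genome <- paste0("TAATAATAATAATAA", gene, "TAATAATAATAATAA")
    cand <- findInterruptions(genome, "TAG")
    fw <- cand[cand$strand == "+", ]
    expect_identical(nrow(fw), 2L)
    expect_identical(unique(fw$chain_id), fw$chain_id[1])
    ## transitive join spans all three fragments: 29 + 1 + 29 + 1 + 30 aa
    expect_identical(fw$up_len_aa[1] + sum(fw$n_joining_stops) +
                     fw$down_len_aa[1] + fw$down_len_aa[2], 90L)
})

test_that("decideCode applies the gain-and-candidates rule with tie-breaks", {
    row <- function(cd, gain, k, tab, sup, trna = 0L)
        data.frame(stop_codon = cd, alt_table = tab, supported = sup,
                   n_interruption_candidates = k,
                   coding_fraction_11 = 0.8, coding_fraction_alt = 0.8 + gain,
                   coding_fraction_gain = gain, mean_orf_length_ratio = 1,
                   n_orfs_with_internal_stop = k, n_internal_stops_total = k,
                   suppressor_trna_support = trna)
    ## all gains ~ 0 -> standard code
    st <- rbind(row("TAG", 0.001, 2L, 15L, TRUE),
                row("TGA", -0.002, 1L, 4L, TRUE),
                row("TAA", 0.003, 0L, 0L, FALSE))
    expect_identical(decideCode(st)$recommended_table, 11L)
    ## clear TAG signal -> table 15
    st$coding_fraction_gain[1] <- 0.08
    st$n_interruption_candidates[1] <- 12L
    v <- decideCode(st)
    expect_identical(v$status, "reassigned")
    expect_identical(v$codon, "TAG")
    expect_identical(v$recommended_table, 15L)
    ## zero suppressor tRNAs: still table 15, with a note
    expect_true(any(grepl("no suppressor tRNA", v$notes)))
    ## two supported codons pass -> higher gain wins, warning note
    st$coding_fraction_gain[2] <- 0.05
    st$n_interruption_candidates[2] <- 9L
    v2 <- decideCode(st)
    expect_identical(v2$codon, "TAG")
    expect_true(any(grepl("multiple codons", v2$notes)))
    ## TAA passing is flagged as unsupported, never recommended
    st$coding_fraction_gain[3] <- 0.2
    st$n_interruption_candidates[3] <- 30L
    v3 <- decideCode(st)
    expect_identical(v3$codon, "TAG")
    expect_true(any(grepl("no supported translation table", v3$notes)))
})

test_that("genomes without any TAG on either strand score zero gain", {
    ## codons over {A,C,G} cannot form TAG or CTA, so neither strand
    ## carries a TAG codon anywhere
    gene <- paste(c("ATG", rep(c("GCA", "CAG", "GGA", "ACC"), 20), "TAA"),
                  collapse = "")
    genome <- paste0("TAA", gene, "GG")
    sc <- recodingScore(genome, "TAG")
    expect_identical(sc$coding_fraction_gain, 0)
    expect_identical(sc$n_interruption_candidates, 0L)
})

test_that("a recoded synthetic genome is called reassigned(TAG, 15) with full evidence", {
    g <- generateGenome(syntheticSpec(nGenes = 20, recodedFraction = 0.3,
                                      nSuppressorTrnas = 1L, seed = 31))
    expect_identical(sum(g$truth$genes$recoded), 6L)
    rep <- recodingReport(g$genome)
    v <- verdict(rep)
    expect_identical(v$status, "reassigned")
    expect_identical(v$codon, "TAG")
    expect_identical(v$recommended_table, 15L)
    st <- recodingStats(rep)
    tag <- st[st$stop_codon == "TAG", ]
    expect_gte(tag$n_orfs_with_internal_stop, 6L)
    expect_identical(tag$suppressor_trna_support, 1L)
    ## designed ambers are recovered in the final annotation (a tile can
    ## occasionally be displaced, hence the 90% recall floor)
    ann <- annotateRecoded(g$genome, geneticCode(15))
    found <- unlist(S4Vectors::mcols(orfs(ann))$reassigned_starts)
    expect_gte(mean(g$truth$ambers$start %in% found), 0.9)
    sm <- recodedOrfStats(ann)
    expect_gte(sm$n_recoded_orfs, 5L)
})

test_that("standard-code genomes re-annotate identically under the verdict table", {
    g <- generateGenome(syntheticSpec(nGenes = 12, recodedFraction = 0,
                                      seed = 41))
    v <- verdict(recodingReport(g$genome))
    expect_identical(v$recommended_table, 11L)
    ann <- annotateRecoded(g$genome, geneticCode(v$recommended_table))
    expect_identical(recodedOrfStats(ann)$n_recoded_orfs, 0L)
    expect_identical(recodedOrfStats(ann)$pct_recoded, 0)
})

test_that("readthrough never loses rescue coverage beyond edge effects", {
    ## coding fraction under table 15 >= table 11 minus epsilon
    for (s in 1:5) {
        g <- generateGenome(syntheticSpec(nGenes = 12,
                                          recodedFraction = (s %% 2) * 0.3,
                                          seed = 60 + s))
        sc <- recodingScore(g$genome, "TAG")
        expect_gte(sc$coding_fraction_gain, -0.02)
    }
})
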