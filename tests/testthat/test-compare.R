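test_that("pairwiseNI handles identity and pure substitution exactly", {
    g <- randomDna(1000, 7)
    expect_equal(as.numeric(pairwiseNI(g, g)), 1)
    ## plant exactly 10 substitutions
    chars <- strsplit(g, "")[[1]]
    at <- seq(50, 950, length.out = 10)
    chars[at] <- vapply(chars[at], function(b)
        setdiff(c("A", "C", "G", "T"), b)[1], "")
    expect_equal(as.numeric(pairwiseNI(g, paste(chars, collapse = ""))), 0.990)
})

test_that("NI equals 1 - realized substitution fraction on mutation-log truth", {
    for (d in c(0.01, 0.05, 0.10)) {
        g <- generateGenome(syntheticSpec(nGenes = 6, seed = 17))
        a <- as.character(g$genome[[1]])
        m <- mutateGenome(a, subRate = d, seed = round(1000 * d))
        expect_equal(as.numeric(pairwiseNI(a, as.character(m$genome[[1]]))),
                     1 - m$realizedSubFraction, tolerance = 1e-12)
    }
})

test_that("NI agrees exactly with the dynamic-programming oracle on indel pairs", {
    set.seed(202)
    for (i in 1:30) {
        L <- sample(300:2000, 1)
        a <- substr(as.character(generateGenome(
            syntheticSpec(nGenes = 3, geneLengthAa = c(50, 80),
                          seed = 300 + i))$genome[[1]]), 1, L)
        m <- mutateGenome(a, subRate = runif(1, 0, 0.1),
                          indelRate = runif(1, 0, 0.01), seed = 300 + i)
        b <- as.character(m$genome[[1]])
        expect_equal(as.numeric(pairwiseNI(a, b)), oracleNI(a, b),
                     tolerance = 1e-12, info = paste("pair", i))
        expect_equal(as.numeric(pairwiseNI(a, b)), as.numeric(pairwiseNI(b, a)),
                     tolerance = 1e-9)
    }
})

test_that("NI decreases monotonically with the substitution rate", {
    for (s in 1:3) {
        g <- generateGenome(syntheticSpec(nGenes = 8, seed = 400 + s))
        a <- as.character(g$genome[[1]])
        nis <- vapply(c(0.01, 0.05, 0.10, 0.20), function(d)
            as.numeric(pairwiseNI(a, as.character(
                mutateGenome(a, subRate = d, seed = 7)$genome[[1]]))), 0)
        expect_true(all(diff(nis) < 0))
    }
})

test_that("intergenomic similarity follows the VIRIDIC length-weighted definition", {
    g <- generateGenome(syntheticSpec(nGenes = 12, seed = 23))
    a <- as.character(g$genome[[1]])
    expect_equal(intergenomicSimilarity(a, a), 1)
    half <- substr(a, 1, nchar(a) %/% 2)
    expect_equal(intergenomicSimilarity(a, half),
                 2 * nchar(half) / (nchar(a) + nchar(half)),
                 tolerance = 0.01)
    expect_lt(intergenomicSimilarity(randomDna(5000, 1), randomDna(5000, 2)),
              0.05)
})

test_that("SG is self-normalized, bounded, symmetric and tracks divergence", {
    g <- generateGenome(syntheticSpec(nGenes = 15, seed = 29))
    a <- g$genome
    expect_identical(sgScore(a, a), 1)
    m1 <- mutateGenome(a, g$truth, subRate = 0.05, seed = 1,
                       preserveOrfs = TRUE)$genome
    m2 <- mutateGenome(a, g$truth, subRate = 0.15, seed = 2,
                       preserveOrfs = TRUE)$genome
    s1 <- sgScore(a, m1); s2 <- sgScore(a, m2)
    expect_true(s1 > s2)
    expect_true(all(c(s1, s2) >= 0 & c(s1, s2) <= 1))
    expect_equal(sgScore(m1, a), s1, tolerance = 1e-9)
    expect_error(sgScore("ACGT", a), "100 nt")
})

test_that("similarity matrices are symmetric with unit diagonal", {
    g0 <- generateGenome(syntheticSpec(nGenes = 8, seed = 37))
    set <- c(g0$genome,
             mutateGenome(g0$genome, g0$truth, 0.03, seed = 5,
                          preserveOrfs = TRUE)$genome,
             mutateGenome(g0$genome, g0$truth, 0.12, seed = 6,
                          preserveOrfs = TRUE)$genome)
    for (metric in c("NI", "intergenomic_similarity")) {
        m <- similarityMatrix(set, metric)
        v <- similarityValues(m)
        expect_equal(v, t(v))
        expect_equal(unname(diag(v)), rep(1, 3))
        expect_true(all(v >= 0 & v <= 1))
    }
})

test_that("threshold clustering reproduces the published genus/species logic", {
    ids <- c("A", "B", "C")
    m <- matrix(c(100, 86.4, 82.7, 86.4, 100, 80.4, 82.7, 80.4, 100), 3,
                dimnames = list(ids, ids))
    cl <- clusterTaxa(m)
    expect_identical(length(unique(genusClusters(cl))), 1L)
    expect_identical(length(unique(speciesClusters(cl))), 3L)

    m2 <- matrix(c(100, 88.1, 88.1, 100), 2,
                 dimnames = list(c("X", "Y"), c("X", "Y")))
    cl2 <- clusterTaxa(m2)
    expect_identical(length(unique(genusClusters(cl2))), 1L)
    expect_identical(length(unique(speciesClusters(cl2))), 2L)

    m3 <- matrix(c(100, 96, 96, 100), 2,
                 dimnames = list(c("X", "Y"), c("X", "Y")))
    expect_identical(length(unique(speciesClusters(clusterTaxa(m3)))), 1L)

    expect_error(clusterTaxa(m, speciesThreshold = 60, genusThreshold = 70),
                 "exceed")
    expect_error(clusterTaxa(m, speciesThreshold = 120), "thresholds")
})

test_that("species partitions always refine genus partitions", {
    set.seed(51)
    for (r in 1:10) {
        n <- sample(3:8, 1)
        v <- matrix(runif(n * n, 40, 100), n)
        v[lower.tri(v)] <- t(v)[lower.tri(v)]
        diag(v) <- 100
        dimnames(v) <- list(paste0("g", 1:n), paste0("g", 1:n))
        for (lk in c("single", "complete")) {
            cl <- clusterTaxa(v, linkage = lk)
            sp <- speciesClusters(cl); ge <- genusClusters(cl)
            for (s in unique(sp))
                expect_identical(length(unique(ge[sp == s])), 1L)
        }
    }
})
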