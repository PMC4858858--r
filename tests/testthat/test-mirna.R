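test_that("RPM normalization is count / (library size / 1e6)", {
    m <- cbind(s1 = c(5, 0, 995), s2 = c(10, 10, 980))
    rpm <- rpmNormalize(m, librarySizes = c(2e6, 1e6))
    expect_equal(unname(rpm[1, ]), c(2.5, 10))
    expect_equal(unname(rpm[2, ]), c(0, 10))
    # when all reads are annotated the column sums are exactly 1e6
    lib <- colSums(m)
    expect_equal(unname(colSums(rpmNormalize(m, lib))), c(1e6, 1e6))
    expect_error(rpmNormalize(m, 0), "librarySizes")
})

test_that("set-D selection applies both inclusive cutoffs", {
    rpm <- rbind(inD    = c(ES = 2^6.5, ELA = 2^4.5),   # mean ~5.5, FC ~ -2
                 lowExp = c(2^6, 2^3),                  # mean ~4.5 < 5
                 flat   = c(2^8, 2^8))                  # FC 0
    tab <- selectSetD(rpm)
    expect_identical(rownames(tab)[tab$inSetD], "inD")
    expect_false(tab["lowExp", "inSetD"])
    expect_false(tab["flat", "inSetD"])

    # idempotent and order-independent
    perm <- sample(nrow(rpm))
    tab2 <- selectSetD(rpm[perm, , drop = FALSE])
    expect_setequal(rownames(tab2)[tab2$inSetD], rownames(tab)[tab$inSetD])
})

test_that("aligner scores a perfect-complement site like the exhaustive oracle", {
    set.seed(31)
    for (k in 1:3) {
        mir <- randomSeq(22)
        utr <- paste0(randomSeq(4), rcDNA(mir), randomSeq(4))  # 30 nt window
        hits <- alignDuplex(mir, utr, duplexParams(reportMin = 1))
        expect_gt(nrow(hits), 0)
        best <- hits[which.max(hits$score), ]
        expect_equal(best$score, oracleDuplexScore(mir, utr))
        expect_lte(best$energy, -10)
        expect_true(best$passes || best$score < 140)
    }
})

test_that("aligner matches the oracle on arbitrary short windows", {
    set.seed(32)
    p <- duplexParams(reportMin = 1)
    for (k in 1:5) {
        mir <- randomSeq(18)
        utr <- randomSeq(26)
        hits <- alignDuplex(mir, utr, p)
        implBest <- if (nrow(hits)) max(hits$score) else 0
        oracleBest <- oracleDuplexScore(mir, utr, p)
        if (oracleBest >= 1) expect_equal(implBest, oracleBest)
        else expect_lt(implBest, 1)
    }
})

test_that("no hit reaches the score threshold without complementarity", {
    hits <- alignDuplex(strrep("A", 22), strrep("A", 200))
    expect_identical(nrow(hits), 0L)
    # short (3 nt) complementary stretch only
    utr <- paste0(strrep("A", 50), "TTT", strrep("A", 50))
    hits2 <- alignDuplex(strrep("A", 22), utr, duplexParams(reportMin = 1))
    expect_true(all(hits2$score < 140))
})

test_that("seed complementarity outscores 3'-half complementarity", {
    set.seed(33)
    mir <- "UGAGGUAGUAGGUUGUAUAGUU"             # let-7-like
    seedSite <- rcDNA(substr(mir, 2, 8))        # positions 2-8
    tailSite <- rcDNA(substr(mir, 14, 20))      # 7 nt from the 3' half
    flank5 <- randomSeq(20); flank3 <- randomSeq(20)
    sSeed <- max(alignDuplex(mir, paste0(flank5, seedSite, flank3),
                             duplexParams(reportMin = 1))$score)
    sTail <- max(alignDuplex(mir, paste0(flank5, tailSite, flank3),
                             duplexParams(reportMin = 1))$score)
    expect_gt(sSeed, sTail)
})

test_that("local alignment score ignores flanking sequence outside the hit", {
    mir <- strrep("C", 22)
    site <- strrep("G", 15)
    hitA <- alignDuplex(mir, paste0(strrep("A", 10), site, strrep("A", 5)),
                        duplexParams(reportMin = 1))
    hitB <- alignDuplex(mir, paste0(strrep("T", 3), site, strrep("T", 40)),
                        duplexParams(reportMin = 1))
    expect_equal(max(hitA$score), max(hitB$score))
    expect_equal(hitA$utrStart[1], 11)
    expect_equal(hitA$utrEnd[1], 25)
})

test_that("pass flag is the conjunction of both thresholds", {
    # 7 A:U seed pairs: score exactly 140, energy -7.7 (fails energy)
    mir <- paste0("C", strrep("A", 7), strrep("C", 14))
    utr <- paste0(strrep("C", 20), strrep("T", 7), strrep("C", 20))
    hits <- alignDuplex(mir, utr)
    expect_equal(hits$score[1], 140)
    expect_equal(hits$energy[1], -7.7)
    expect_false(hits$passes[1])
    # relaxing either threshold never removes a passing hit
    relaxedScore <- alignDuplex(mir, utr, duplexParams(minScore = 100))
    relaxedEnergy <- alignDuplex(mir, utr, duplexParams(maxEnergy = -5))
    expect_true(all(hits$passes <= relaxedScore$passes))
    expect_true(all(hits$passes <= relaxedEnergy$passes))
    expect_true(relaxedEnergy$passes[1])
})

test_that("invalid sequence alphabets are rejected", {
    expect_error(alignDuplex("ACGTN", "ACGT"), "alphabet")
    expect_error(alignDuplex("ACGU", "ACGTX"), "alphabet")
})

test_that("cumulative binding score sums passing hits of the selected set", {
    hits <- data.frame(
        mirna = c("m1", "m1", "m2", "m3"),
        gene = c("g1", "g1", "g1", "g2"),
        score = c(150, 160, 200, 150),
        energy = c(-12, -15, -11, -8),
        passes = c(TRUE, TRUE, TRUE, FALSE))
    out <- cumulativeBindingScore(hits, mirnaSet = c("m1", "m2"),
                                  genes = c("g1", "g2", "g3"))
    expect_equal(out$score, c(150 + 160 + 200, 0, 0))
    # without m2: only the two m1 hits count
    out2 <- cumulativeBindingScore(hits, mirnaSet = "m1",
                                   genes = c("g1", "g2"))
    expect_equal(out2$score, c(310, 0))
    # oracle recomputation on a random hit table
    set.seed(34)
    big <- data.frame(mirna = sample(paste0("m", 1:5), 200, TRUE),
                      gene = sample(paste0("g", 1:20), 200, TRUE),
                      score = runif(200, 100, 200),
                      passes = sample(c(TRUE, FALSE), 200, TRUE))
    res <- cumulativeBindingScore(big, genes = paste0("g", 1:20))
    for (g in paste0("g", 1:20)) {
        expected <- sum(big$score[big$passes & big$gene == g])
        expect_equal(res$score[res$gene == g], expected)
    }
})

test_that("scrambling preserves composition and is seed-deterministic", {
    expect_identical(unname(scrambleUtrs(c(g = "AAAA"), seed = 1)), "AAAA")
    set.seed(35)
    utrs <- setNames(vapply(1:10, function(i) randomSeq(80), ""),
                     paste0("g", 1:10))
    scr <- scrambleUtrs(utrs, seed = 9)
    for (i in seq_along(utrs)) {
        expect_identical(sort(strsplit(scr[[i]], "")[[1]]),
                         sort(strsplit(utrs[[i]], "")[[1]]))
    }
    expect_false(all(scr == utrs))
    expect_identical(scrambleUtrs(utrs, seed = 9), scr)
    # DNAStringSet round trip
    xs <- scrambleUtrs(Biostrings::DNAStringSet(utrs), seed = 9)
    expect_s4_class(xs, "DNAStringSet")
    expect_identical(as.character(xs), scr)
})

test_that("family rank-sum test reproduces the exact enumeration p-value", {
    out <- familyBindingTest(c(a = 300, b = 310, c = 320),
                             families = list(A = c("a", "b", "c")),
                             nullScores = c(0, 0, 5))
    # most extreme 3 vs 3 ranking: exact two-sided p = 2/20
    expect_equal(out$p, 0.1)
    expect_equal(out$p, oracleRankSumP(c(300, 310, 320), c(0, 0, 5)))
    expect_equal(out$median, 310)
    expect_equal(out$nullMedian, 0)

    # identical family and null distributions: p = 1
    same <- familyBindingTest(c(a = 1, b = 2, c = 3),
                              families = list(A = c("a", "b", "c")),
                              nullScores = c(1, 2, 3))
    expect_equal(same$p, 1)

    # undersized families are skipped with a warning
    expect_warning(
        empty <- familyBindingTest(c(a = 1), families = list(A = "a"),
                                   nullScores = 1:3),
        "fewer than")
    expect_identical(nrow(empty), 0L)
})

test_that("rank-sum p equals full enumeration for small untied groups", {
    set.seed(36)
    for (k in 1:4) {
        x <- rnorm(sample(3:7, 1))
        y <- rnorm(sample(3:7, 1))
        impl <- suppressWarnings(wilcox.test(x, y))$p.value
        expect_equal(impl, oracleRankSumP(x, y), tolerance = 1e-12)
    }
})

test_that("z-scores standardize rows with the population sd", {
    z <- mirnaZScores(rbind(a = c(10, 10, 10, 10), b = c(0, 0, 10, 10)))
    expect_equal(unname(z["a", ]), c(0, 0, 0, 0))
    expect_equal(unname(z["b", ]), c(-1, -1, 1, 1))   # population sd = 5
    set.seed(37)
    r <- matrix(rnorm(40, 5, 2), 10)
    zr <- mirnaZScores(r)
    expect_equal(unname(rowMeans(zr)), rep(0, 10))
    expect_equal(unname(apply(zr, 1, function(x)
        sqrt(mean((x - mean(x))^2)))), rep(1, 10))
})

test_that("planted family sites drive the binding-score family test", {
    sim <- simulateMirnaAndUtrs(nMirnas = 40, genesPerFamily = 15,
                                nBackgroundGenes = 30,
                                utrLengthRange = c(200, 300), seed = 38)
    setD <- sim$truth@setD
    hits <- scanDuplexes(sim$mirnas[setD], sim$utrs)
    sc <- cumulativeBindingScore(hits, mirnaSet = setD,
                                 genes = names(sim$utrs),
                                 families = sim$families)
    bg <- sc$score[is.na(sc$family)]
    ft <- familyBindingTest(sc, nullScores = bg)
    for (f in sim$truth@targetFamilies)
        expect_lt(ft$p[ft$family == f], 0.01)
})
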