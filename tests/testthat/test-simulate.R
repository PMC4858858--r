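test_that("array generator is seed-deterministic and handles degenerate fractions", {
    a <- simulateArrayExperiment(nGenes = 300, seed = 42)
    b <- simulateArrayExperiment(nGenes = 300, seed = 42)
    expect_identical(SummarizedExperiment::assay(a$se),
                     SummarizedExperiment::assay(b$se))
    expect_identical(a$truth@releasedGenes, b$truth@releasedGenes)
    c <- simulateArrayExperiment(nGenes = 300, seed = 43)
    expect_false(identical(SummarizedExperiment::assay(a$se),
                           SummarizedExperiment::assay(c$se)))

    # fraction bound 0: both channels drawn from the same background law
    z <- simulateArrayExperiment(nGenes = 5000, fractionBound = 0, seed = 1)
    expect_length(z$truth@boundGenes[[1]], 0)
    m <- SummarizedExperiment::assay(z$se)
    cd <- SummarizedExperiment::colData(z$se)
    ago <- m[, cd$fraction == "ago_ip" & cd$stage == "ES"]
    tot <- m[, cd$fraction == "total" & cd$stage == "ES"]
    expect_lt(abs(mean(ago) - mean(tot)), 4 * sqrt(2 * var(tot) / 5000))
    expect_lt(abs(sd(ago) / sd(tot) - 1), 0.05)
})

test_that("array generator reproduces its configured moments", {
    sim <- simulateArrayExperiment(nGenes = 10000, backgroundMean = 6,
                                   backgroundSd = 0.7, boundShift = 4,
                                   fractionBound = 0.2, seed = 7)
    m <- SummarizedExperiment::assay(sim$se)
    cd <- SummarizedExperiment::colData(sim$se)
    bound <- sim$truth@boundGenes[[1]]
    agoES <- m[bound, which(cd$stage == "ES" & cd$fraction == "ago_ip")[1]]
    se <- sd(agoES) / sqrt(length(agoES))
    expect_lt(abs(mean(agoES) - 10), 3 * se)
})

test_that("array generator output rejects a single-Gaussian fit when bimodal", {
    sim <- simulateArrayExperiment(nGenes = 5000, seed = 5)
    m <- SummarizedExperiment::assay(sim$se)
    ago <- m[, 1]
    fit <- fitBackgroundMixture(ago, seed = 1)
    ll1 <- sum(dnorm(ago, mean(ago), sqrt(mean((ago - mean(ago))^2)),
                     log = TRUE))
    lrt <- 2 * (fit@logLik - ll1)
    expect_gt(lrt, qchisq(1 - 1e-6, df = 3))
})

test_that("array truth is recomputable from the emitted matrix", {
    sim <- simulateArrayExperiment(nGenes = 4000, seed = 9)
    m <- SummarizedExperiment::assay(sim$se)
    cd <- SummarizedExperiment::colData(sim$se)
    E <- sapply(unique(cd$stage), function(s)
        rowMeans(m[, cd$stage == s & cd$fraction == "ago_ip", drop = FALSE]) -
        rowMeans(m[, cd$stage == s & cd$fraction == "total", drop = FALSE]))
    # planted bound genes have enrichment ~3, background ~0: recut at 1.5
    recomputedBound <- rownames(m)[E[, 1] > 1.5]
    expect_setequal(recomputedBound, sim$truth@boundGenes[[1]])
    dE <- E[, 2] - E[, 1]
    recomputedReleased <- rownames(m)[E[, 1] > 1.5 & dE < -1.5]
    expect_setequal(recomputedReleased, sim$truth@releasedGenes[[1]])
    # released and loaded sets are disjoint by construction
    expect_length(intersect(sim$truth@releasedGenes[[1]],
                            sim$truth@loadedGenes[[1]]), 0)
})

test_that("count generator: Poisson limit, size-factor symmetry, planted effect", {
    # dispersion -> 0: per-gene variance/mean ratio -> 1
    sim <- simulateCountExperiment(nGenes = 2000, dispersion = 0,
                                   sizeFactors = rep(1, 8),
                                   nEffectGenes = 0, seed = 3)
    m <- SummarizedExperiment::assay(sim$se)
    inputCols <- grepl("input", colnames(m))
    noEffect <- setdiff(rownames(m), sim$truth@effectGenes)
    sub <- m[noEffect, !inputCols]
    ratio <- apply(sub, 1L, var) / rowMeans(sub)
    expect_lt(abs(mean(ratio) - 1), 0.1)

    # equal true size factors: library sizes agree within sampling error
    cs <- colSums(m)
    expect_lt(max(abs(cs / mean(cs) - 1)), 0.05)

    # planted log2 effect of 2 shows up as a 4x enrichment ratio
    sim2 <- simulateCountExperiment(nGenes = 5000, nEffectGenes = 100,
                                    effectSize = 2, seed = 8)
    m2 <- SummarizedExperiment::assay(sim2$se)
    info <- as.data.frame(SummarizedExperiment::colData(sim2$se))
    gm <- function(cond, frac) rowMeans(
        m2[, info$condition == cond & info$fraction == frac, drop = FALSE])
    enrRatio <- (gm("ELA", "ribo_ip") / gm("ELA", "input")) /
                (gm("ES", "ribo_ip") / gm("ES", "input"))
    eff <- sim2$truth@effectGenes
    bg <- setdiff(rownames(m2), eff)
    x <- enrRatio[eff][is.finite(enrRatio[eff])]
    expect_lt(abs(mean(x) - 4 * median(enrRatio[bg], na.rm = TRUE)),
              3 * sd(x) / sqrt(length(x)))
})

test_that("count generator validates its configuration", {
    expect_error(simulateCountExperiment(nGenes = 10, sizeFactors = rep(0, 8)),
                 "sizeFactors")
    expect_error(simulateCountExperiment(nGenes = 0), "nGenes")
    expect_error(simulateCountExperiment(nGenes = 10, dispersion = -1),
                 "dispersion")
})

test_that("miRNA/UTR generator plants exact reverse-complement sites", {
    sim <- simulateMirnaAndUtrs(nMirnas = 30, genesPerFamily = 8,
                                nBackgroundGenes = 10, seed = 11)
    ps <- sim$truth@plantedSites
    expect_gt(nrow(ps), 0)
    mirseq <- as.character(sim$mirnas)
    utrseq <- as.character(sim$utrs)
    for (i in seq_len(nrow(ps))) {
        sub <- substr(utrseq[[ps$gene[i]]], ps$start[i], ps$end[i])
        expected <- rcDNA(substr(mirseq[[ps$mirna[i]]], 2, 16))
        expect_identical(sub, expected)
    }
    # planted miRNAs are all set-D members, sites only in target families
    expect_true(all(ps$mirna %in% sim$truth@setD))
    targetGenes <- unlist(sim$families[sim$truth@targetFamilies])
    expect_true(all(ps$gene %in% targetGenes))
})

test_that("miRNA generator: set-D truth is recomputable; degenerate configs", {
    sim <- simulateMirnaAndUtrs(seed = 13)
    rpm <- rpmNormalize(sim$counts, sim$librarySizes)
    tab <- selectSetD(rpm, refCondition = "ES", testCondition = "ELA")
    expect_identical(sort(rownames(tab)[tab$inSetD]), sim$truth@setD)

    none <- simulateMirnaAndUtrs(sitesPerGene = 0, seed = 13)
    expect_identical(nrow(none$truth@plantedSites), 0L)
    expect_length(none$truth@targetFamilies, 0)

    expect_error(simulateMirnaAndUtrs(utrLengthRange = c(5, 10), seed = 1),
                 "utrLengthRange")
    expect_error(simulateMirnaAndUtrs(librarySizes = 0), "librarySizes")
})

test_that("miRNA generator is seed-deterministic", {
    a <- simulateMirnaAndUtrs(nMirnas = 20, genesPerFamily = 4,
                              nBackgroundGenes = 5, seed = 21)
    b <- simulateMirnaAndUtrs(nMirnas = 20, genesPerFamily = 4,
                              nBackgroundGenes = 5, seed = 21)
    expect_identical(a$counts, b$counts)
    expect_identical(as.character(a$utrs), as.character(b$utrs))
    expect_identical(as.character(a$mirnas), as.character(b$mirnas))
})
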