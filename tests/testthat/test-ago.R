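test_that("quantile normalization matches the sort-average-unsort oracle", {
    # hand example: columns [1,2,3] and [4,5,6] both become [2.5,3.5,4.5]
    m <- cbind(a = c(1, 2, 3), b = c(6, 4, 5))
    qn <- quantileNormalize(m)
    expect_equal(unname(qn[, "a"]), c(2.5, 3.5, 4.5))
    expect_equal(unname(qn[, "b"]), c(4.5, 2.5, 3.5))

    set.seed(101)
    r <- matrix(rnorm(200), 50, 4,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
    expect_equal(quantileNormalize(r), oracleQuantileNormalize(r),
                 ignore_attr = TRUE)
})

test_that("quantile normalization is idempotent and equalizes distributions", {
    set.seed(7)
    r <- matrix(rnorm(240, sd = c(1, 2, 3, 4)), 60, 4)
    qn <- quantileNormalize(r)
    sorted <- apply(qn, 2L, sort)
    for (j in 2:4) expect_equal(sorted[, j], sorted[, 1])
    expect_equal(quantileNormalize(qn), qn)

    # two identical columns are left unchanged
    m <- cbind(c(5, 1, 3), c(5, 1, 3))
    expect_equal(quantileNormalize(m), m)
})

test_that("quantile normalization gives ties the mean of tied reference ranks", {
    m <- cbind(c(1, 1, 3), c(10, 20, 30))
    qn <- quantileNormalize(m)
    ref <- rowMeans(apply(m, 2L, sort))      # 5.5, 10.5, 16.5
    expect_equal(unname(qn[1:2, 1]), rep(mean(ref[1:2]), 2))
    expect_equal(qn[3, 1], ref[3])
})

test_that("single-sample input is returned unchanged with a warning", {
    m <- matrix(1:3, ncol = 1)
    expect_warning(out <- quantileNormalize(m), "single sample")
    expect_equal(out, m)
})

test_that("mixture EM recovers known component parameters", {
    set.seed(11)
    x <- c(rnorm(5000, 5, 0.5), rnorm(5000, 9, 0.5))
    fit <- fitBackgroundMixture(x, seed = 2)
    expect_true(fit@converged)
    expect_lt(abs(backgroundMean(fit) - 5), 0.1)
    expect_lt(abs(backgroundSd(fit) - 0.5), 0.05)
    expect_lt(abs(fit@mu[2] - 9), 0.1)
    expect_lt(abs(mixtureWeights(fit)[1] - 0.5), 0.05)
    # EM guarantee: the log-likelihood trace never decreases
    expect_true(all(diff(fit@logLikTrace) > -1e-8))
})

test_that("mixture EM agrees with an independent mixture implementation", {
    skip_if_not_installed("mclust")
    suppressMessages(library(mclust))
    set.seed(12)
    x <- c(rnorm(3000, 6, 0.6), rnorm(1000, 9.5, 0.4))
    fit <- fitBackgroundMixture(x, seed = 3)
    mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
    expect_lt(abs(backgroundMean(fit) - min(mc$parameters$mean)), 0.05)
    expect_lt(abs(backgroundSd(fit) -
                  sqrt(mc$parameters$variance$sigmasq[
                      which.min(mc$parameters$mean)])), 0.05)
    expect_lt(abs(fit@logLik - mc$loglik), 1)
})

test_that("mixture EM tolerates unimodal input without crashing", {
    set.seed(13)
    x <- rnorm(2000, 7, 0.8)
    fit <- fitBackgroundMixture(x, seed = 4)
    # components overlap or one weight is negligible
    expect_true(abs(fit@mu[2] - fit@mu[1]) < 1.5 ||
                min(mixtureWeights(fit)) < 0.1)
})

test_that("bound-call threshold is mu1 + 3*sigma1 with the printed tail rate", {
    fit <- new("MixtureFit", weights = c(0.5, 0.5), mu = c(5, 9),
               sigma = c(0.5, 0.5), logLik = 0, logLikTrace = 0,
               nIterations = 1L, converged = TRUE)
    expect_equal(boundCallThreshold(fit), 6.5)

    # Monte-Carlo tail of the background component at T1
    set.seed(14)
    draws <- rnorm(1e6, 5, 0.5)
    fp <- mean(draws > 6.5)
    se <- sqrt(0.00135 * (1 - 0.00135) / 1e6)
    expect_lt(abs(fp - 0.00135), 3 * se)
})

test_that("threshold container validates its invariants", {
    expect_error(agoThresholds(t1 = 7, t2 = 0.4, t3 = 0.5), "t2")
    expect_error(agoThresholds(t1 = 7, deltaMin = 0), "deltaMin")
    expect_equal(agoThresholds(t1 = 7, relaxed = TRUE)@t3, 1.2)
    expect_equal(agoThresholds(t1 = 7)@t3, 0.5)
})

test_that("Ago enrichment equals the log2 IP/total ratio", {
    genes <- paste0("g", 1:4)
    m <- cbind("ES.ago_ip.1" = c(10, 10, 8, 6),
               "ES.total.1" = c(10, 8, 8, 7))
    rownames(m) <- genes
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(log2intensity = m),
        colData = S4Vectors::DataFrame(
            stage = "ES", fraction = c("ago_ip", "total"),
            replicate = 1L, row.names = colnames(m)))
    tab <- agoEnrichment(se, agoThresholds(t1 = 9))
    expect_equal(tab$E, c(0, 2, 0, -1))
    expect_equal(tab$bound, c(TRUE, TRUE, FALSE, FALSE))
    # linear-scale oracle: de-log, ratio, re-log
    expect_equal(tab$E, log2(2^m[, 1] / 2^m[, 2]), ignore_attr = TRUE)
})

test_that("Ago enrichment flags stages missing a channel as not assessable", {
    m <- cbind("ES.ago_ip.1" = c(1, 2), "ES.total.1" = c(1, 1),
               "ELA.ago_ip.1" = c(2, 2))
    rownames(m) <- c("g1", "g2")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(log2intensity = m),
        colData = S4Vectors::DataFrame(
            stage = c("ES", "ES", "ELA"),
            fraction = c("ago_ip", "total", "ago_ip"),
            replicate = 1L, row.names = colnames(m)))
    tab <- agoEnrichment(se, agoThresholds(t1 = 0))
    expect_true(all(tab$assessable[tab$stage == "ES"]))
    expect_false(any(tab$assessable[tab$stage == "ELA"]))
    expect_true(all(is.na(tab$E[tab$stage == "ELA"])))
})

makeEnrichTable <- function(E1, E2, bound1, bound2, genes = NULL) {
    if (is.null(genes)) genes <- paste0("g", seq_along(E1))
    rbind(data.frame(gene = genes, stage = "ES", E = E1, agoIntensity = NA,
                     bound = bound1, assessable = TRUE),
          data.frame(gene = genes, stage = "ELA", E = E2, agoIntensity = NA,
                     bound = bound2, assessable = TRUE))
}

test_that("transition rules classify the printed example cases", {
    th <- agoThresholds(t1 = 0, t2 = 2, t3 = 0.5, deltaMin = 1.5)
    tab <- makeEnrichTable(E1 = c(2.5, 0.2, 2.5),
                           E2 = c(0.3, 2.6, 1.4),
                           bound1 = c(TRUE, FALSE, TRUE),
                           bound2 = c(FALSE, TRUE, TRUE))
    calls <- classifyTransitions(tab, th)
    expect_equal(as.character(calls$call),
                 c("released",   # E 2.5 -> 0.3, bound at n
                   "loaded",     # E 0.2 -> 2.6, bound at n+1
                   "unchanged")) # fails E_{n+1} <= T3
    expect_equal(calls$deltaE, c(-2.2, 2.4, -1.1))
    # released implies deltaE < 0, loaded implies deltaE > 0
    expect_true(all(calls$deltaE[calls$call == "released"] < 0))
    expect_true(all(calls$deltaE[calls$call == "loaded"] > 0))
})

test_that("transition calls equal a brute-force re-evaluation on 200 genes", {
    set.seed(15)
    n <- 200
    tab <- makeEnrichTable(E1 = runif(n, -1, 4), E2 = runif(n, -1, 4),
                           bound1 = sample(c(TRUE, FALSE), n, replace = TRUE),
                           bound2 = sample(c(TRUE, FALSE), n, replace = TRUE))
    th <- agoThresholds(t1 = 0, t2 = 2, t3 = 0.5, deltaMin = 1.5)
    calls <- classifyTransitions(tab, th)
    a <- tab[tab$stage == "ES", ]
    b <- tab[tab$stage == "ELA", ]
    for (i in seq_len(n)) {
        dE <- b$E[i] - a$E[i]
        expected <- if (a$bound[i] && a$E[i] >= 2 && b$E[i] <= 0.5 &&
                        abs(dE) >= 1.5) "released"
            else if (b$bound[i] && a$E[i] <= 0.5 && b$E[i] >= 2 &&
                     abs(dE) >= 1.5) "loaded"
            else if (a$bound[i] || b$bound[i]) "unchanged"
            else "not_assessed"
        expect_identical(as.character(calls$call[i]), expected)
    }
})

test_that("release/load calls are sign- and order-symmetric", {
    # each identity requires a sign-symmetric threshold pair (T2 = -T3):
    # negating all enrichments swaps released/loaded, and so does reversing
    # the stage order
    set.seed(16)
    n <- 300
    E1 <- runif(n, -3, 3); E2 <- runif(n, -3, 3)
    th <- agoThresholds(t1 = -1e9, t2 = 1, t3 = -1, deltaMin = 0.5)
    fwd <- classifyTransitions(makeEnrichTable(E1, E2, TRUE, TRUE), th)
    neg <- classifyTransitions(makeEnrichTable(-E1, -E2, TRUE, TRUE), th)
    swp <- classifyTransitions(makeEnrichTable(E2, E1, TRUE, TRUE), th)
    for (other in list(neg, swp)) {
        expect_identical(as.character(fwd$call) == "released",
                         as.character(other$call) == "loaded")
        expect_identical(as.character(fwd$call) == "loaded",
                         as.character(other$call) == "released")
    }
    # composing both operations maps each class onto itself
    both <- classifyTransitions(makeEnrichTable(-E2, -E1, TRUE, TRUE), th)
    expect_identical(as.character(fwd$call), as.character(both$call))
})

test_that("non-adjacent stage pairs are rejected", {
    tab <- rbind(makeEnrichTable(1, 1, TRUE, TRUE),
                 data.frame(gene = "g1", stage = "NPC", E = 1,
                            agoIntensity = NA, bound = TRUE,
                            assessable = TRUE))
    th <- agoThresholds(t1 = 0)
    expect_error(classifyTransitions(tab, th, transitions = "ES->NPC"),
                 "non-adjacent")
})

test_that("released/loaded calls recover planted transitions", {
    sim <- simulateArrayExperiment(nGenes = 2000, seed = 17)
    fit <- fitBackgroundMixture(
        SummarizedExperiment::assay(sim$se)[, 1], seed = 1)
    th <- agoThresholds(boundCallThreshold(fit))
    calls <- classifyTransitions(agoEnrichment(sim$se, th), th)
    rel <- calls$gene[calls$call == "released"]
    lod <- calls$gene[calls$call == "loaded"]
    trueRel <- sim$truth@releasedGenes[[1]]
    trueLod <- sim$truth@loadedGenes[[1]]
    expect_gte(mean(trueRel %in% rel), 0.9)
    expect_gte(mean(trueLod %in% lod), 0.9)
    if (length(rel)) expect_lte(mean(!(rel %in% trueRel)), 0.1)
    if (length(lod)) expect_lte(mean(!(lod %in% trueLod)), 0.1)
})
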