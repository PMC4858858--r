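#' Run the integrated post-transcriptional analysis pipeline
#'
#' Orchestrates the full synthetic analysis end to end: simulate an
#' Ago-RIP/total array experiment, call bound genes via the background
#' mixture threshold and classify released/loaded transcripts; simulate a
#' coupled ribosome-IP/input count experiment in which the Ago-released
#' genes carry a positive planted change in ribosome occupancy, normalize
#' and filter it and compute \code{log2RiboDeltaE}; simulate a small-RNA
#' library plus 3'UTR families, select set-D miRNAs, scan their binding
#' sites and test family enrichment against the random-gene background; and
#' assemble the integration table relating Ago enrichment change classes to
#' ribosome-occupancy change.
#'
#' All randomness derives from the single top-level \code{seed}, from which
#' per-stage seeds are derived deterministically, so two runs with the same
#' arguments are identical. Simulated arrays are generated directly on a
#' common (post-normalization) scale, so quantile normalization is not
#' re-applied to them by default; set \code{qn = TRUE} when feeding raw
#' arrays with array-to-array scale effects.
#'
#' @param seed top-level integer seed.
#' @param nGenes gene-universe size shared by the array and count stages.
#' @param arrayArgs,countArgs,mirnaArgs named lists of extra arguments
#'   forwarded to [simulateArrayExperiment()], [simulateCountExperiment()]
#'   and [simulateMirnaAndUtrs()].
#' @param coupledRiboEffect planted log2 ribosome-enrichment change given to
#'   the truly Ago-released genes in the count stage.
#' @param t2,t3,deltaMin,relaxed Ago thresholds (see [agoThresholds()]).
#' @param riboMinMean,riboMaxCv,riboThreshold polysome filters and selection
#'   cutoff (see [filterGenes()], [selectTranslationallyRegulated()]).
#' @param setDMinMean,setDMaxFc set-D selection cutoffs (see
#'   [selectSetD()]).
#' @param duplex a [duplexParams()] list for the UTR scan.
#' @param deltaClassCut |deltaE| cutoff defining the released-like /
#'   loaded-like classes of the integration table (default 2).
#' @param qn apply joint quantile normalization to the array intensities.
#' @param outDir optional directory; when given, all stage tables are
#'   written (TSV/JSON/FASTA/GMT/Newick) and the report records the paths.
#' @return A list of class \code{"riscReport"}: per-stage result tables
#'   (\code{ago}, \code{ribo}, \code{mirna}, \code{integration}) and a
#'   \code{report} list of summary counts consistent with those tables.
#'
#' @examples
#' res <- runPipeline(seed = 7, nGenes = 800,
#'                    mirnaArgs = list(genesPerFamily = 5,
#'                                     nBackgroundGenes = 10))
#' res$report$nReleased
#' @export
runPipeline <- function(seed = 1,
                        nGenes = 10000,
                        arrayArgs = list(),
                        countArgs = list(),
                        mirnaArgs = list(),
                        coupledRiboEffect = 1.5,
                        t2 = 2, t3 = if (relaxed) 1.2 else 0.5,
                        deltaMin = 1.5, relaxed = FALSE,
                        riboMinMean = 50, riboMaxCv = 0.20,
                        riboThreshold = 1,
                        setDMinMean = 5, setDMaxFc = -1,
                        duplex = duplexParams(),
                        deltaClassCut = 2,
                        qn = FALSE,
                        outDir = NULL) {
    t0 <- Sys.time()
    if (!is.null(outDir) && !dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)

    ## -- Ago-RIP stage -----------------------------------------------------
    arr <- do.call(simulateArrayExperiment,
                   c(list(nGenes = nGenes, seed = deriveSeed(seed, 1L)),
                     arrayArgs))
    se <- if (qn) quantileNormalize(arr$se) else arr$se
    cd <- SummarizedExperiment::colData(se)
    agoCol <- which(cd$fraction == "ago_ip")[1]
    fit <- fitBackgroundMixture(
        SummarizedExperiment::assay(se)[, agoCol],
        seed = deriveSeed(seed, 2L))
    th <- agoThresholds(boundCallThreshold(fit), t2 = t2, t3 = t3,
                        deltaMin = deltaMin, relaxed = relaxed)
    enrich <- agoEnrichment(se, th)
    calls <- classifyTransitions(enrich, th)
    releasedCalled <- calls$gene[calls$call == "released"]
    loadedCalled <- calls$gene[calls$call == "loaded"]

    ## -- polysome stage (coupled to the true released genes) ---------------
    releasedTrue <- if (length(arr$truth@releasedGenes))
        arr$truth@releasedGenes[[1]] else character()
    cnt <- do.call(simulateCountExperiment,
                   c(list(nGenes = nGenes, effectGenes = releasedTrue,
                          effectSize = coupledRiboEffect,
                          seed = deriveSeed(seed, 3L)),
                     countArgs))
    counts <- SummarizedExperiment::assay(cnt$se)
    info <- as.data.frame(SummarizedExperiment::colData(cnt$se))
    sf <- sizeFactorsMedianRatio(counts)
    norm <- normalizeCounts(counts, sf)
    filt <- filterGenes(norm, info, minMean = riboMinMean, maxCv = riboMaxCv)
    ribo <- ribosomeEnrichment(norm, info, keep = filt$gene[filt$keep])
    reg <- selectTranslationallyRegulated(ribo, threshold = riboThreshold)

    ## -- miRNA targeting stage ---------------------------------------------
    mir <- do.call(simulateMirnaAndUtrs,
                   c(list(seed = deriveSeed(seed, 4L)), mirnaArgs))
    rpm <- rpmNormalize(mir$counts, mir$librarySizes)
    setDTab <- selectSetD(rpm, refCondition = colnames(rpm)[2],
                          testCondition = colnames(rpm)[4],
                          minMean = setDMinMean, maxFc = setDMaxFc)
    setD <- rownames(setDTab)[setDTab$inSetD]
    hits <- scanDuplexes(mir$mirnas[setD], mir$utrs, duplex)
    scores <- cumulativeBindingScore(hits, mirnaSet = setD,
                                     genes = names(mir$utrs),
                                     families = mir$families)
    bgScores <- scores$score[is.na(scores$family)]
    famTest <- familyBindingTest(scores, nullScores = bgScores)
    zs <- mirnaZScores(rpm[setD, , drop = FALSE])

    ## -- integration table (Ago deltaE classes vs ribosome change) ---------
    dE <- setNames(calls$deltaE, calls$gene)[ribo$gene]
    cls <- rep(NA_character_, nrow(ribo))
    cls[dE <= -deltaClassCut] <- "released"
    cls[dE >= deltaClassCut] <- "loaded"
    cls[abs(dE) <= 1] <- "unchanged"
    integration <- data.frame(gene = ribo$gene, deltaE = dE,
                              deltaEClass = cls,
                              log2RiboDeltaE = ribo$log2RiboDeltaE,
                              passedFilters = ribo$passedFilters,
                              stringsAsFactors = FALSE)
    classStats <- lapply(c("released", "loaded", "unchanged"), function(cc) {
        v <- integration$log2RiboDeltaE[integration$deltaEClass %in% cc &
                                        integration$passedFilters]
        if (length(v) >= 3L) {
            tt <- t.test(v, mu = 0)
            data.frame(class = cc, n = length(v), mean = mean(v),
                       p = tt$p.value, stringsAsFactors = FALSE)
        } else {
            data.frame(class = cc, n = length(v),
                       mean = if (length(v)) mean(v) else NA_real_,
                       p = NA_real_, stringsAsFactors = FALSE)
        }
    })
    classStats <- do.call(rbind, classStats)

    report <- list(
        seed = seed,
        nGenes = nGenes,
        mixture = list(mu1 = fit@mu[1], sigma1 = fit@sigma[1],
                       t1 = th@t1, converged = fit@converged),
        nBoundPerStage = vapply(
            split(enrich$bound, enrich$stage)[unique(enrich$stage)],
            function(b) sum(b, na.rm = TRUE), 1L),
        nReleased = length(releasedCalled),
        nLoaded = length(loadedCalled),
        sizeFactors = sf,
        nPassedFilters = sum(ribo$passedFilters),
        nTranslationUp = length(reg$up),
        nTranslationDown = length(reg$down),
        nSetD = length(setD),
        familyTest = famTest,
        integration = classStats,
        started = format(t0, "%Y-%m-%d %H:%M:%S"),
        finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))

    result <- list(
        ago = list(se = se, truth = arr$truth, fit = fit, thresholds = th,
                   enrichment = enrich, calls = calls),
        ribo = list(truth = cnt$truth, sizeFactors = sf, filters = filt,
                    table = ribo, regulated = reg),
        mirna = list(truth = mir$truth, rpm = rpm, setD = setD,
                     setDTable = setDTab, hits = hits, scores = scores,
                     familyTest = famTest, zScores = zs),
        integration = integration,
        report = report)
    class(result) <- "riscReport"

    if (!is.null(outDir)) {
        paths <- list(
            enrichment = file.path(outDir, "ago_enrichment.tsv"),
            calls = file.path(outDir, "transition_calls.tsv"),
            sizeFactors = file.path(outDir, "size_factors.tsv"),
            ribo = file.path(outDir, "ribosome_enrichment.tsv"),
            setD = file.path(outDir, "set_d.tsv"),
            hits = file.path(outDir, "duplex_hits.tsv"),
            scores = file.path(outDir, "gene_binding_scores.tsv"),
            familyTest = file.path(outDir, "family_binding_test.tsv"),
            integration = file.path(outDir, "integration.tsv"),
            utrs = file.path(outDir, "utrs.fasta"),
            mirnas = file.path(outDir, "mirnas.fasta"),
            families = file.path(outDir, "families.gmt"),
            report = file.path(outDir, "report.json"))
        wtab <- function(df, p) write.table(df, p, sep = "\t", quote = FALSE,
                                            row.names = FALSE)
        wtab(enrich, paths$enrichment)
        wtab(calls, paths$calls)
        wtab(data.frame(sample = names(sf), sizeFactor = sf), paths$sizeFactors)
        wtab(ribo, paths$ribo)
        wtab(setDTab, paths$setD)
        wtab(hits, paths$hits)
        wtab(scores, paths$scores)
        wtab(famTest, paths$familyTest)
        wtab(integration, paths$integration)
        Biostrings::writeXStringSet(mir$utrs, paths$utrs)
        Biostrings::writeXStringSet(mir$mirnas, paths$mirnas)
        writeGmt(mir$families, paths$families)
        jsonlite::write_json(report, paths$report, auto_unbox = TRUE,
                             digits = NA, force = TRUE)
        result$paths <- paths
    }
    result
}

#' @noRd
#' @export
print.riscReport <- function(x, ...) {
    r <- x$report
    cat("Integrated post-transcriptional analysis (seed", r$seed, ")\n")
    cat(sprintf("  genes: %d; bound per stage: %s\n", r$nGenes,
                paste(r$nBoundPerStage, collapse = ", ")))
    cat(sprintf("  Ago transitions: %d released, %d loaded\n",
                r$nReleased, r$nLoaded))
    cat(sprintf("  polysome: %d genes pass filters; %d up / %d down (log2RiboDeltaE)\n",
                r$nPassedFilters, r$nTranslationUp, r$nTranslationDown))
    cat(sprintf("  miRNAs in set D: %d\n", r$nSetD))
    cat("  family binding test:\n")
    ft <- r$familyTest
    for (i in seq_len(nrow(ft)))
        cat(sprintf("    %-8s n=%3d median=%8.1f null=%6.1f p=%.3g\n",
                    ft$family[i], ft$n[i], ft$median[i], ft$nullMedian[i],
                    ft$p[i]))
    cat("  integration (log2RiboDeltaE by Ago deltaE class):\n")
    it <- r$integration
    for (i in seq_len(nrow(it)))
        cat(sprintf("    %-9s n=%4d mean=%+.3f p=%.3g\n", it$class[i],
                    it$n[i], it$mean[i], it$p[i]))
    invisible(x)
}
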