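#' Simulate an Ago-RIP/total intensity array experiment
#'
#' Generates log2 microarray intensities for an Ago immunoprecipitate channel
#' and a total-RNA channel at each differentiation stage, with a known bound
#' subpopulation and planted release/load events, emulating the bimodal
#' Ago-channel intensity structure of an Ago-RIP experiment.
#'
#' Each gene has a baseline log2 intensity drawn from
#' \code{N(backgroundMean, backgroundSd^2)}. A fraction
#' \code{fractionBound} of genes is Ago-bound at the first stage, with a
#' per-gene Ago enrichment drawn from \code{N(boundShift, boundSd^2)}; their
#' Ago-channel intensity is the baseline plus this enrichment, so the
#' Ago-channel distribution is a two-component Gaussian mixture. At each
#' transition a fraction \code{releaseFraction} of the currently bound genes
#' has its enrichment shifted by \code{releaseEffect} (typically to ~0,
#' leaving the bound population), and \code{loadFraction} (of the bound count)
#' previously unbound genes gain \code{loadEffect}. Per-array measurement
#' noise \code{N(0, noiseSd^2)} is added independently to every value.
#'
#' @param nGenes number of genes.
#' @param stages character vector of ordered stage labels.
#' @param nReplicates arrays per (stage, fraction); the reference design uses
#'   one array per channel from pooled samples.
#' @param backgroundMean,backgroundSd background (unbound) log2-intensity
#'   distribution.
#' @param boundShift,boundSd mean and sd of the planted Ago enrichment of
#'   bound genes (log2 units).
#' @param fractionBound fraction of genes Ago-bound at the first stage.
#' @param releaseFraction fraction of bound genes released at each transition.
#' @param loadFraction number of newly loaded genes per transition, as a
#'   fraction of the bound-gene count.
#' @param releaseEffect,loadEffect planted change in enrichment (deltaE, log2
#'   units) for released / loaded genes.
#' @param noiseSd per-array measurement noise sd (log2 units).
#' @param seed integer seed; the full output is reproducible from it.
#'
#' @return A list with elements \code{se}, a
#'   \linkS4class{SummarizedExperiment} with assay \code{"log2intensity"} and
#'   colData columns \code{stage}, \code{fraction} (\code{"ago_ip"} or
#'   \code{"total"}) and \code{replicate}; and \code{truth}, a
#'   \linkS4class{SimTruth} recording bound/released/loaded gene sets.
#'
#' @examples
#' sim <- simulateArrayExperiment(nGenes = 500, seed = 1)
#' sim$se
#' sim$truth
#' @export
simulateArrayExperiment <- function(nGenes = 10000,
                                    stages = c("ES", "ELA"),
                                    nReplicates = 1,
                                    backgroundMean = 6,
                                    backgroundSd = 0.5,
                                    boundShift = 3,
                                    boundSd = 0.2,
                                    fractionBound = 0.2,
                                    releaseFraction = 0.05,
                                    loadFraction = 0.05,
                                    releaseEffect = -3,
                                    loadEffect = 3,
                                    noiseSd = 0.1,
                                    seed = 1) {
    .checkScalar(nGenes, "nGenes", min = 1, integer = TRUE)
    if (length(stages) < 1L) stop("'stages' must name at least one stage")
    .checkScalar(nReplicates, "nReplicates", min = 1, integer = TRUE)
    .checkScalar(backgroundSd, "backgroundSd", min = 0, strictMin = TRUE)
    .checkScalar(boundSd, "boundSd", min = 0, strictMin = TRUE)
    .checkScalar(noiseSd, "noiseSd", min = 0)
    .checkFraction(fractionBound, "fractionBound")
    .checkFraction(releaseFraction, "releaseFraction")
    .checkFraction(loadFraction, "loadFraction")

    nStages <- length(stages)
    genes <- .geneIds(nGenes)

    withSeed(seed, {
        baseline <- rnorm(nGenes, backgroundMean, backgroundSd)

        # planted enrichment per gene and stage
        E <- matrix(0, nGenes, nStages, dimnames = list(genes, stages))
        nBound <- round(fractionBound * nGenes)
        bound1 <- sample(genes, nBound)
        E[bound1, 1] <- rnorm(nBound, boundShift, boundSd)

        boundGenes <- vector("list", nStages)
        releasedGenes <- loadedGenes <- vector("list", max(nStages - 1L, 0L))
        boundGenes[[1]] <- bound1
        if (nStages > 1) for (t in seq_len(nStages - 1L)) {
            bt <- boundGenes[[t]]
            E[, t + 1L] <- E[, t]
            rel <- sample(bt, round(releaseFraction * length(bt)))
            E[rel, t + 1L] <- E[rel, t] + releaseEffect
            pool <- setdiff(genes, bt)
            lod <- sample(pool, min(round(loadFraction * length(bt)),
                                    length(pool)))
            E[lod, t + 1L] <- E[lod, t] + loadEffect
            releasedGenes[[t]] <- rel
            loadedGenes[[t]] <- lod
            boundGenes[[t + 1L]] <- c(setdiff(bt, rel), lod)
        }

        samples <- expand.grid(replicate = seq_len(nReplicates),
                               fraction = c("ago_ip", "total"),
                               stage = stages, stringsAsFactors = FALSE)
        samples <- samples[, c("stage", "fraction", "replicate")]
        sampleNames <- with(samples, paste(stage, fraction, replicate,
                                           sep = "."))
        mat <- matrix(NA_real_, nGenes, nrow(samples),
                      dimnames = list(genes, sampleNames))
        for (j in seq_len(nrow(samples))) {
            s <- match(samples$stage[j], stages)
            signal <- baseline +
                if (samples$fraction[j] == "ago_ip") E[, s] else 0
            mat[, j] <- signal + rnorm(nGenes, 0, noiseSd)
        }

        se <- SummarizedExperiment::SummarizedExperiment(
            assays = list(log2intensity = mat),
            colData = S4Vectors::DataFrame(samples, row.names = sampleNames))
        truth <- new("SimTruth", boundGenes = boundGenes,
                     releasedGenes = releasedGenes, loadedGenes = loadedGenes,
                     seed = as.integer(seed))
        list(se = se, truth = truth)
    })
}

#' Simulate a ribosome-IP/input RNA-seq count experiment
#'
#' Generates negative-binomial read counts for a translating-ribosome
#' pull-down design (ribosome IP and input fractions in two conditions, with
#' replicates), scaled by known per-sample size factors and carrying a planted
#' log2 change in ribosome enrichment on a designated gene subset.
#'
#' Per-gene expected input counts are drawn from a log-normal distribution
#' (\code{meanLog}, \code{sdLog}). Ribosome-IP means equal input means except
#' for the effect genes, whose IP mean in the second condition is multiplied
#' by \code{2^effectSize}, so their true log2 ribosome-enrichment change is
#' \code{effectSize}. Counts are sampled from a negative binomial with
#' variance \code{mu + dispersion * mu^2} around the size-factor-scaled mean
#' (Poisson when \code{dispersion = 0}).
#'
#' @param nGenes number of genes.
#' @param conditions character(2), ordered condition labels (reference first).
#' @param nReplicates replicates per (condition, fraction).
#' @param meanLog,sdLog log-normal parameters of per-gene baseline means.
#' @param dispersion negative-binomial dispersion alpha (>= 0).
#' @param sizeFactors per-sample positive scaling factors, recycled/checked
#'   against the sample layout; \code{NULL} draws them log-normally and
#'   rescales to geometric mean 1.
#' @param effectGenes character vector of gene ids to carry the planted
#'   effect, or \code{NULL} to sample \code{nEffectGenes} of them.
#' @param nEffectGenes number of effect genes sampled when
#'   \code{effectGenes} is \code{NULL}.
#' @param effectSize planted log2 ribosome-enrichment change.
#' @param seed integer seed.
#'
#' @return A list with \code{se}, a \linkS4class{SummarizedExperiment} of
#'   integer counts with colData \code{condition}, \code{fraction}
#'   (\code{"ribo_ip"}/\code{"input"}) and \code{replicate}; and \code{truth},
#'   a \linkS4class{SimTruth} with \code{trueSizeFactors} (named by sample)
#'   and \code{effectGenes}.
#'
#' @examples
#' sim <- simulateCountExperiment(nGenes = 200, seed = 1)
#' head(SummarizedExperiment::assay(sim$se))
#' @export
simulateCountExperiment <- function(nGenes = 5000,
                                    conditions = c("ES", "ELA"),
                                    nReplicates = 2,
                                    meanLog = log(300),
                                    sdLog = 1,
                                    dispersion = 0.01,
                                    sizeFactors = NULL,
                                    effectGenes = NULL,
                                    nEffectGenes = 100,
                                    effectSize = 2,
                                    seed = 1) {
    .checkScalar(nGenes, "nGenes", min = 1, integer = TRUE)
    if (length(conditions) != 2L)
        stop("'conditions' must give exactly two condition labels")
    .checkScalar(nReplicates, "nReplicates", min = 1, integer = TRUE)
    .checkScalar(dispersion, "dispersion", min = 0)
    .checkScalar(nEffectGenes, "nEffectGenes", min = 0, integer = TRUE)

    genes <- .geneIds(nGenes)
    samples <- expand.grid(replicate = seq_len(nReplicates),
                           fraction = c("ribo_ip", "input"),
                           condition = conditions, stringsAsFactors = FALSE)
    samples <- samples[, c("condition", "fraction", "replicate")]
    sampleNames <- with(samples, paste(condition, fraction, replicate,
                                       sep = "."))
    nSamples <- nrow(samples)
    if (!is.null(sizeFactors)) {
        if (length(sizeFactors) != nSamples || any(sizeFactors <= 0) ||
            any(!is.finite(sizeFactors)))
            stop(sprintf(
                "'sizeFactors' must be %d strictly positive finite values",
                nSamples))
    }

    withSeed(seed, {
        if (is.null(sizeFactors)) {
            sizeFactors <- exp(rnorm(nSamples, 0, 0.25))
            sizeFactors <- sizeFactors / exp(mean(log(sizeFactors)))
        }
        names(sizeFactors) <- sampleNames

        baseMu <- exp(rnorm(nGenes, meanLog, sdLog))
        names(baseMu) <- genes
        if (is.null(effectGenes)) {
            effectGenes <- sample(genes, min(nEffectGenes, nGenes))
        } else {
            effectGenes <- intersect(as.character(effectGenes), genes)
        }

        counts <- matrix(0L, nGenes, nSamples,
                         dimnames = list(genes, sampleNames))
        for (j in seq_len(nSamples)) {
            mu <- baseMu
            if (samples$fraction[j] == "ribo_ip" &&
                samples$condition[j] == conditions[2])
                mu[effectGenes] <- mu[effectGenes] * 2^effectSize
            mu <- mu * sizeFactors[j]
            counts[, j] <- if (dispersion == 0) rpois(nGenes, mu)
                           else rnbinom(nGenes, mu = mu, size = 1 / dispersion)
        }

        se <- SummarizedExperiment::SummarizedExperiment(
            assays = list(counts = counts),
            colData = S4Vectors::DataFrame(samples, row.names = sampleNames))
        truth <- new("SimTruth", trueSizeFactors = sizeFactors,
                     effectGenes = effectGenes, seed = as.integer(seed))
        list(se = se, truth = truth)
    })
}

#' Simulate a small-RNA library and 3'UTR set with planted target sites
#'
#' Generates (i) a miRNA count table over four conditions (naive 2i+LIF,
#' serum ES, and the two derived primed states), with a planted subset of
#' down-regulated ground-state miRNAs ("set D"); (ii) 3'UTR sequences for
#' genes organised into families, where the UTRs of target-family genes carry
#' exact reverse-complement binding sites of randomly chosen set-D miRNAs
#' while all other sequence is i.i.d. uniform; and (iii) the ground truth of
#' every planted assignment.
#'
#' A set-D miRNA has mean log2 RPM \code{setDMeanLog2Rpm} across the compared
#' pair of conditions and log2 fold change \code{setDLog2Fc}; remaining
#' miRNAs are split between a well-expressed group with fold change ~0 and a
#' low-expression group, so that the printed selection rule (mean log2 RPM >=
#' 5 and log2 FC <= -1) recovers exactly the planted set. Counts are Poisson
#' around the target RPM at the given library sizes. Planted sites are the
#' reverse complement of miRNA positions \code{siteStart..siteEnd} (seed plus
#' a 3'-supplementary stretch) placed at non-overlapping random offsets.
#'
#' @param nMirnas number of miRNAs.
#' @param mirnaLength mature miRNA length (nt).
#' @param conditions character(4): naive 2i+LIF, naive serum, primed from
#'   2i+LIF, primed from serum. The fold change compares conditions 4 vs 2.
#' @param librarySizes total reads per condition library (recycled to 4).
#' @param setDFraction fraction of miRNAs planted as set D.
#' @param setDMeanLog2Rpm planted mean log2 RPM of set-D miRNAs.
#' @param setDLog2Fc planted log2 fold change of set-D miRNAs (<= -1).
#' @param highExprRange,lowExprRange mean log2 RPM ranges of the non-set-D
#'   well-expressed and low-expression miRNAs.
#' @param targetFamilies,controlFamilies family names with / without planted
#'   sites.
#' @param genesPerFamily genes per family.
#' @param nBackgroundGenes unannotated background genes (the random-set null).
#' @param utrLengthRange integer(2), min/max UTR length (nt).
#' @param sitesPerGene planted sites per target-family gene.
#' @param siteStart,siteEnd miRNA positions (5'-based) whose reverse
#'   complement is planted.
#' @param seed integer seed.
#'
#' @return A list with \code{counts} (miRNA x condition integer matrix),
#'   \code{librarySizes}, \code{mirnas} (named \code{RNAStringSet}),
#'   \code{utrs} (named \code{DNAStringSet}), \code{families} (named list of
#'   gene id vectors, GMT-like), and \code{truth} (a \linkS4class{SimTruth}
#'   with \code{setD}, \code{plantedSites}, \code{targetFamilies}).
#'
#' @examples
#' sim <- simulateMirnaAndUtrs(nMirnas = 20, genesPerFamily = 5, seed = 1)
#' sim$truth
#' @export
simulateMirnaAndUtrs <- function(nMirnas = 60,
                                 mirnaLength = 22,
                                 conditions = c("ES_2iL", "ES", "ELA_2iL",
                                                "ELA"),
                                 librarySizes = 2e6,
                                 setDFraction = 0.15,
                                 setDMeanLog2Rpm = 7,
                                 setDLog2Fc = -2,
                                 highExprRange = c(5.5, 9),
                                 lowExprRange = c(1, 4),
                                 targetFamilies = c("DNMT", "KDM", "SWISNF"),
                                 controlFamilies = "CYP450",
                                 genesPerFamily = 20,
                                 nBackgroundGenes = 40,
                                 utrLengthRange = c(300, 600),
                                 sitesPerGene = 3,
                                 siteStart = 2,
                                 siteEnd = 16,
                                 seed = 1) {
    .checkScalar(nMirnas, "nMirnas", min = 2, integer = TRUE)
    .checkScalar(mirnaLength, "mirnaLength", min = 15, integer = TRUE)
    if (length(conditions) != 4L)
        stop("'conditions' must give exactly four condition labels")
    librarySizes <- rep_len(librarySizes, 4L)
    if (any(librarySizes <= 0))
        stop("'librarySizes' must be strictly positive")
    .checkFraction(setDFraction, "setDFraction")
    .checkScalar(setDLog2Fc, "setDLog2Fc", max = -1)
    .checkScalar(setDMeanLog2Rpm, "setDMeanLog2Rpm", min = 5)
    .checkScalar(sitesPerGene, "sitesPerGene", min = 0, integer = TRUE)
    .checkScalar(siteStart, "siteStart", min = 1, integer = TRUE)
    .checkScalar(siteEnd, "siteEnd", min = siteStart, max = mirnaLength,
                 integer = TRUE)
    siteLen <- siteEnd - siteStart + 1L
    if (length(utrLengthRange) != 2L || utrLengthRange[1] > utrLengthRange[2])
        stop("'utrLengthRange' must be an increasing length-2 range")
    if (sitesPerGene > 0 && utrLengthRange[1] < siteLen)
        stop("'utrLengthRange': UTR may be shorter than a planted site (",
             siteLen, " nt)")

    withSeed(seed, {
        mirnaIds <- .geneIds(nMirnas, "mir")
        mirnaSeqs <- vapply(seq_len(nMirnas), function(i)
            paste(sample(c("A", "C", "G", "U"), mirnaLength, replace = TRUE),
                  collapse = ""), "")
        names(mirnaSeqs) <- mirnaIds

        nSetD <- round(setDFraction * nMirnas)
        setD <- sample(mirnaIds, nSetD)
        rest <- setdiff(mirnaIds, setD)
        high <- rest[seq_len(floor(length(rest) / 2))]
        low <- setdiff(rest, high)

        # target mean log2 RPM (m) and log2 FC between conditions 4 and 2
        m <- fc <- setNames(numeric(nMirnas), mirnaIds)
        m[setD] <- setDMeanLog2Rpm
        fc[setD] <- setDLog2Fc
        m[high] <- runif(length(high), highExprRange[1], highExprRange[2])
        fc[high] <- rnorm(length(high), 0, 0.2)
        m[low] <- runif(length(low), lowExprRange[1], lowExprRange[2])
        fc[low] <- rnorm(length(low), 0, 0.5)

        rpmES <- 2^(m - fc / 2)
        rpmELA <- 2^(m + fc / 2)
        # naive 2i+LIF tracks serum ES; primed-from-2i tracks primed
        targetRpm <- cbind(rpmES, rpmES, rpmELA, rpmELA)
        colnames(targetRpm) <- conditions
        counts <- matrix(0L, nMirnas, 4L,
                         dimnames = list(mirnaIds, conditions))
        for (j in 1:4)
            counts[, j] <- rpois(nMirnas, targetRpm[, j] * librarySizes[j] / 1e6)

        families <- c(
            setNames(lapply(targetFamilies, function(f)
                .geneIds(genesPerFamily, f)), targetFamilies),
            setNames(lapply(controlFamilies, function(f)
                .geneIds(genesPerFamily, f)), controlFamilies))
        bgGenes <- if (nBackgroundGenes > 0) .geneIds(nBackgroundGenes, "BG")
                   else character()
        allGenes <- c(unlist(families, use.names = FALSE), bgGenes)

        utrLens <- sample(seq(utrLengthRange[1], utrLengthRange[2]),
                          length(allGenes), replace = TRUE)
        names(utrLens) <- allGenes
        utrs <- vapply(utrLens, function(L)
            paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                  collapse = ""), "")

        planted <- list()
        if (sitesPerGene > 0 && length(setD)) {
            targetGenes <- unlist(families[targetFamilies], use.names = FALSE)
            for (g in targetGenes) {
                L <- utrLens[[g]]
                nSites <- min(sitesPerGene, L %/% (siteLen + 2L))
                if (nSites == 0) next
                # non-overlapping offsets with >= 2 nt spacing
                slot <- siteLen + 2L
                offs <- sort(sample(seq_len(L - siteLen + 1L), nSites * 4L,
                                    replace = TRUE))
                starts <- integer(0)
                for (o in offs) {
                    if (all(abs(o - starts) >= slot)) starts <- c(starts, o)
                    if (length(starts) == nSites) break
                }
                for (st in starts) {
                    mir <- sample(setD, 1L)
                    site <- .reverseComplementDNA(
                        substr(mirnaSeqs[[mir]], siteStart, siteEnd))
                    substr(utrs[[g]], st, st + siteLen - 1L) <- site
                    planted[[length(planted) + 1L]] <- data.frame(
                        mirna = mir, gene = g, start = st,
                        end = st + siteLen - 1L, siteSeq = site,
                        stringsAsFactors = FALSE)
                }
            }
        }
        plantedSites <- if (length(planted)) do.call(rbind, planted)
                        else new("SimTruth")@plantedSites

        truth <- new("SimTruth", setD = sort(setD),
                     plantedSites = plantedSites,
                     targetFamilies = if (length(planted))
                         as.character(targetFamilies) else character(),
                     seed = as.integer(seed))
        list(counts = counts,
             librarySizes = setNames(librarySizes, conditions),
             mirnas = Biostrings::RNAStringSet(mirnaSeqs),
             utrs = Biostrings::DNAStringSet(utrs),
             families = families,
             truth = truth)
    })
}

# reverse complement of an RNA/DNA string, returned as DNA (T alphabet)
.reverseComplementDNA <- function(x) {
    x <- chartr("Uu", "Tt", x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
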