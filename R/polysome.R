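#' Median-of-ratios size factors
#'
#' The scaling factor of a sample is the median, over genes with strictly
#' positive counts in every sample, of the ratio of the gene's count in that
#' sample to its geometric mean across all samples. Dividing each column by
#' its factor places all libraries on a common scale under the assumption
#' that most genes are not differentially expressed.
#'
#' @param counts a non-negative integer matrix (genes x samples) or a
#'   \linkS4class{SummarizedExperiment} carrying one.
#' @return A named numeric vector of positive per-sample size factors.
#' @examples
#' m <- rbind(c(2, 4), c(8, 16), c(4, 8))
#' sizeFactorsMedianRatio(m)  # 1/sqrt(2), sqrt(2)
#' @export
sizeFactorsMedianRatio <- function(counts) {
    if (methods::is(counts, "SummarizedExperiment"))
        counts <- SummarizedExperiment::assay(counts)
    if (!is.matrix(counts) || !is.numeric(counts) || any(counts < 0))
        stop("'counts' must be a non-negative numeric matrix")
    if (ncol(counts) < 2L)
        stop("at least two samples are required")
    logc <- log(counts)
    logGeo <- rowMeans(logc)
    eligible <- is.finite(logGeo)          # genes positive in all samples
    if (!any(eligible))
        stop("no gene has strictly positive counts in all samples; ",
             "size factors are undefined")
    sf <- apply(logc[eligible, , drop = FALSE], 2L,
                function(col) exp(median(col - logGeo[eligible])))
    if (is.null(names(sf)) && !is.null(colnames(counts)))
        names(sf) <- colnames(counts)
    sf
}

#' Normalize counts by size factors
#'
#' @param counts matrix or \linkS4class{SummarizedExperiment} of raw counts.
#' @param sizeFactors per-sample factors, e.g. from
#'   [sizeFactorsMedianRatio()]; computed from the data when missing.
#' @return Matrix (or SummarizedExperiment with assay
#'   \code{"normalized"} added) of counts divided column-wise by the factors.
#' @examples
#' m <- rbind(c(2, 4), c(8, 16))
#' normalizeCounts(m)
#' @export
normalizeCounts <- function(counts, sizeFactors = NULL) {
    if (methods::is(counts, "SummarizedExperiment")) {
        m <- SummarizedExperiment::assay(counts)
        if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMedianRatio(m)
        SummarizedExperiment::assays(counts)$normalized <-
            sweep(m, 2L, sizeFactors, "/")
        return(counts)
    }
    if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMedianRatio(counts)
    if (length(sizeFactors) != ncol(counts) || any(sizeFactors <= 0))
        stop("'sizeFactors' must be one positive factor per sample")
    sweep(counts, 2L, sizeFactors, "/")
}

#' Expression and variability gene filters
#'
#' Keeps a gene when (i) its mean normalized count is at least \code{minMean}
#' in at least one of the two conditions (averaged over both fractions'
#' replicates within the condition), and (ii) in every (condition, fraction)
#' group with two or more replicates, the standard deviation of its counts is
#' at most \code{maxCv} times the group mean. Singleton groups (e.g. after
#' dropping a degenerate replicate) skip the variability test.
#'
#' @param normalized matrix of normalized counts (genes x samples).
#' @param sampleInfo data.frame with one row per sample: columns
#'   \code{condition}, \code{fraction}, \code{replicate}.
#' @param minMean expression filter threshold (default 50 counts).
#' @param maxCv variability filter: maximal sd/mean (default 0.20).
#' @return data.frame per gene with \code{meanByCondition} columns, logical
#'   \code{passExpression}, \code{passVariability} and \code{keep}.
#' @examples
#' sim <- simulateCountExperiment(nGenes = 100, seed = 1)
#' norm <- normalizeCounts(SummarizedExperiment::assay(sim$se))
#' info <- as.data.frame(SummarizedExperiment::colData(sim$se))
#' summary(filterGenes(norm, info)$keep)
#' @export
filterGenes <- function(normalized, sampleInfo, minMean = 50, maxCv = 0.20) {
    stopifnot(is.matrix(normalized),
              nrow(sampleInfo) == ncol(normalized),
              all(c("condition", "fraction") %in% names(sampleInfo)))
    conditions <- unique(as.character(sampleInfo$condition))
    condMeans <- vapply(conditions, function(cc)
        rowMeans(normalized[, sampleInfo$condition == cc, drop = FALSE]),
        numeric(nrow(normalized)))
    passExpression <- apply(condMeans >= minMean, 1L, any)

    groups <- interaction(sampleInfo$condition, sampleInfo$fraction,
                          drop = TRUE)
    passVariability <- rep(TRUE, nrow(normalized))
    for (g in levels(groups)) {
        cols <- which(groups == g)
        if (length(cols) < 2L) next
        sub <- normalized[, cols, drop = FALSE]
        mu <- rowMeans(sub)
        sdev <- apply(sub, 1L, sd)
        cv <- ifelse(mu > 0, sdev / mu, ifelse(sdev > 0, Inf, 0))
        passVariability <- passVariability & cv <= maxCv
    }

    out <- data.frame(gene = rownames(normalized), condMeans,
                      passExpression = passExpression,
                      passVariability = passVariability,
                      keep = passExpression & passVariability,
                      stringsAsFactors = FALSE)
    names(out)[seq_along(conditions) + 1L] <- paste0("mean_", conditions)
    rownames(out) <- NULL
    out
}

#' Ribosome enrichment and its change between conditions
#'
#' For each gene and condition, ribosome enrichment is the mean normalized
#' ribosome-IP count divided by the mean normalized input count; the reported
#' change is \code{log2RiboDeltaE = log2(R_cond2) - log2(R_cond1)}. Genes
#' with a zero mean input in either condition are flagged not assessable.
#'
#' @param normalized matrix of normalized counts (genes x samples).
#' @param sampleInfo data.frame per sample with \code{condition} and
#'   \code{fraction} (\code{"ribo_ip"}/\code{"input"}).
#' @param keep optional logical or character selector of filter-passing genes
#'   (see [filterGenes()]); others are reported with
#'   \code{passedFilters = FALSE}.
#' @param conditions character(2) giving the (reference, test) order;
#'   defaults to order of appearance.
#' @return data.frame per gene: mean IP/input per condition, enrichments
#'   \code{R_<cond>}, \code{log2RiboDeltaE}, \code{passedFilters},
#'   \code{assessable}.
#' @examples
#' sim <- simulateCountExperiment(nGenes = 100, seed = 1)
#' norm <- normalizeCounts(SummarizedExperiment::assay(sim$se))
#' info <- as.data.frame(SummarizedExperiment::colData(sim$se))
#' head(ribosomeEnrichment(norm, info))
#' @export
ribosomeEnrichment <- function(normalized, sampleInfo, keep = NULL,
                               conditions = NULL) {
    stopifnot(is.matrix(normalized),
              nrow(sampleInfo) == ncol(normalized))
    if (is.null(conditions))
        conditions <- unique(as.character(sampleInfo$condition))
    if (length(conditions) != 2L)
        stop("exactly two conditions are required")
    genes <- rownames(normalized)

    groupMean <- function(cond, frac) {
        cols <- which(sampleInfo$condition == cond &
                      sampleInfo$fraction == frac)
        if (!length(cols))
            stop(sprintf("no '%s' samples for condition '%s'", frac, cond))
        rowMeans(normalized[, cols, drop = FALSE])
    }
    ip1 <- groupMean(conditions[1], "ribo_ip")
    in1 <- groupMean(conditions[1], "input")
    ip2 <- groupMean(conditions[2], "ribo_ip")
    in2 <- groupMean(conditions[2], "input")
    if (all(in1 == 0) && all(in2 == 0))
        stop("all input means are zero; enrichment is undefined")

    assessable <- in1 > 0 & in2 > 0
    r1 <- ifelse(assessable, ip1 / in1, NA_real_)
    r2 <- ifelse(assessable, ip2 / in2, NA_real_)
    dE <- log2(r2) - log2(r1)
    dE[!is.finite(dE)] <- NA_real_
    assessable <- assessable & !is.na(dE)

    passed <- if (is.null(keep)) rep(TRUE, length(genes))
              else if (is.character(keep)) genes %in% keep
              else as.logical(keep)
    out <- data.frame(gene = genes, ipMean1 = ip1, inputMean1 = in1,
                      ipMean2 = ip2, inputMean2 = in2,
                      R1 = r1, R2 = r2, log2RiboDeltaE = dE,
                      passedFilters = passed & assessable,
                      assessable = assessable, stringsAsFactors = FALSE)
    names(out)[names(out) == "R1"] <- paste0("R_", conditions[1])
    names(out)[names(out) == "R2"] <- paste0("R_", conditions[2])
    rownames(out) <- NULL
    out
}

#' Select translationally regulated genes
#'
#' Splits the filter-passing genes by their log2 change in ribosome
#' enrichment: \code{up} are genes with \code{log2RiboDeltaE > threshold}
#' (strict, as the published selection), \code{down} those with
#' \code{log2RiboDeltaE < -threshold}.
#'
#' @param table output of [ribosomeEnrichment()].
#' @param threshold positive cutoff (default 1).
#' @return list with character vectors \code{up} and \code{down}.
#' @examples
#' tab <- data.frame(gene = c("a", "b", "c"),
#'                   log2RiboDeltaE = c(1.5, 1.0, -1.5),
#'                   passedFilters = TRUE)
#' selectTranslationallyRegulated(tab)
#' @export
selectTranslationallyRegulated <- function(table, threshold = 1) {
    .checkScalar(threshold, "threshold", min = 0, strictMin = TRUE)
    ok <- table$passedFilters %in% TRUE & is.finite(table$log2RiboDeltaE)
    list(up = table$gene[ok & table$log2RiboDeltaE > threshold],
         down = table$gene[ok & table$log2RiboDeltaE < -threshold])
}
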