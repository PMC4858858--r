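#' Sign-test concordance of two fold-change profiles
#'
#' A gene is concordant when its fold changes in the reference and test
#' comparisons have the same non-zero sign. The two-sided exact binomial
#' test assesses whether the concordant fraction departs from the chance
#' level of 1/2. Genes with a zero fold change in either profile are
#' excluded and counted.
#'
#' @param fcRef,fcTest named numeric vectors of per-gene log2 fold changes;
#'   matched on their common gene names (or positionally when unnamed).
#' @return list with \code{nConcordant}, \code{nDiscordant},
#'   \code{nExcluded}, \code{concordance} (fraction) and the two-sided
#'   binomial \code{p}.
#' @examples
#' signTestConcordance(c(a = 1, b = -2, c = 3), c(a = 2, b = -1, c = 0.5))
#' @export
signTestConcordance <- function(fcRef, fcTest) {
    if (!is.null(names(fcRef)) && !is.null(names(fcTest))) {
        common <- intersect(names(fcRef), names(fcTest))
        if (!length(common)) stop("no genes shared between the two profiles")
        fcRef <- fcRef[common]
        fcTest <- fcTest[common]
    } else if (length(fcRef) != length(fcTest)) {
        stop("unnamed profiles must have equal length")
    }
    ok <- is.finite(fcRef) & is.finite(fcTest)
    sRef <- sign(fcRef[ok])
    sTest <- sign(fcTest[ok])
    nonzero <- sRef != 0 & sTest != 0
    nConc <- sum(sRef[nonzero] == sTest[nonzero])
    nDisc <- sum(nonzero) - nConc
    p <- if (nConc + nDisc == 0) NA_real_
         else binom.test(nConc, nConc + nDisc, p = 0.5,
                         alternative = "two.sided")$p.value
    list(nConcordant = nConc, nDiscordant = nDisc,
         nExcluded = sum(ok) - sum(nonzero),
         concordance = if (nConc + nDisc > 0) nConc / (nConc + nDisc)
                       else NA_real_,
         p = p)
}

#' Randomization controls for the sign-test concordance
#'
#' Re-runs [signTestConcordance()] after destroying the gene-wise pairing:
#' mode \code{"random_gene"} replaces every test fold change by that of a
#' randomly drawn gene (with replacement); mode \code{"scrambled_order"}
#' permutes the test fold changes across genes. Repeated \code{R} times,
#' yielding the null distribution of concordance p-values.
#'
#' @param fcRef,fcTest as in [signTestConcordance()].
#' @param mode \code{"random_gene"} or \code{"scrambled_order"}.
#' @param R number of randomization replicates (default 1000).
#' @param seed integer seed, or \code{NULL}.
#' @return list with \code{mode}, \code{R}, numeric vectors \code{p} and
#'   \code{concordance} (one entry per replicate), and their medians.
#' @examples
#' fc <- rnorm(200)
#' ctrl <- randomizedSignControls(fc, fc, "scrambled_order", R = 50,
#'                                seed = 1)
#' ctrl$medianP
#' @export
randomizedSignControls <- function(fcRef, fcTest,
                                   mode = c("random_gene",
                                            "scrambled_order"),
                                   R = 1000L, seed = NULL) {
    mode <- match.arg(mode)
    .checkScalar(R, "R", min = 1, integer = TRUE)
    if (!is.null(names(fcRef)) && !is.null(names(fcTest))) {
        common <- intersect(names(fcRef), names(fcTest))
        fcRef <- fcRef[common]
        fcTest <- fcTest[common]
    }
    n <- length(fcTest)
    withSeed(seed, {
        p <- conc <- numeric(R)
        for (r in seq_len(R)) {
            perm <- if (mode == "random_gene")
                        fcTest[sample.int(n, n, replace = TRUE)]
                    else fcTest[sample.int(n, n)]
            names(perm) <- names(fcRef)
            st <- signTestConcordance(fcRef, perm)
            p[r] <- st$p
            conc[r] <- st$concordance
        }
        list(mode = mode, R = R, p = p, concordance = conc,
             medianP = median(p, na.rm = TRUE),
             medianConcordance = median(conc, na.rm = TRUE))
    })
}

#' Differential-expression gene filter
#'
#' Selects genes differentially expressed between two conditions with
#' \code{|log2FC| >= fcMin}, Benjamini-Hochberg adjusted two-sample t-test
#' p-value \code{< alpha}, and mean log2 expression \code{>= exprMin}
#' (boundaries inclusive/exclusive exactly as stated). Without replication
#' in either condition the p-value criterion is skipped and flagged.
#'
#' @param expr matrix of log2 expression (genes x samples).
#' @param condition factor/character per sample with exactly two levels;
#'   the second level is the test condition.
#' @param fcMin minimum absolute log2 fold change (default 1).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param exprMin minimum mean log2 expression (default 7.5).
#' @return data.frame per gene: \code{log2Fc}, \code{meanExpr}, \code{p},
#'   \code{adjP}, \code{selected}; attribute \code{"pUsed"} records whether
#'   the p criterion was applied.
#' @examples
#' expr <- matrix(rnorm(40, 8), 10,
#'                dimnames = list(paste0("g", 1:10), NULL))
#' deGeneFilter(expr, rep(c("ES", "ELA"), each = 2))
#' @export
deGeneFilter <- function(expr, condition, fcMin = 1, alpha = 0.05,
                         exprMin = 7.5) {
    stopifnot(is.matrix(expr), ncol(expr) == length(condition))
    condition <- as.factor(condition)
    if (nlevels(condition) != 2L) stop("exactly two conditions are required")
    g1 <- expr[, condition == levels(condition)[1], drop = FALSE]
    g2 <- expr[, condition == levels(condition)[2], drop = FALSE]
    log2Fc <- rowMeans(g2) - rowMeans(g1)
    meanExpr <- rowMeans(expr)

    pUsed <- ncol(g1) >= 2L && ncol(g2) >= 2L
    if (pUsed) {
        n1 <- ncol(g1); n2 <- ncol(g2)
        v1 <- apply(g1, 1L, stats::var); v2 <- apply(g2, 1L, stats::var)
        se2 <- v1 / n1 + v2 / n2
        tstat <- log2Fc / sqrt(se2)
        df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
        p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
        adjP <- p.adjust(p, method = "BH")
        selected <- abs(log2Fc) >= fcMin & adjP < alpha & meanExpr >= exprMin
    } else {
        p <- adjP <- rep(NA_real_, nrow(expr))
        selected <- abs(log2Fc) >= fcMin & meanExpr >= exprMin
        warning("no replication: p-value criterion skipped")
    }
    out <- data.frame(gene = rownames(expr), log2Fc = log2Fc,
                      meanExpr = meanExpr, p = p, adjP = adjP,
                      selected = selected, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "pUsed") <- pUsed
    out
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of sample profiles with Euclidean distance and
#' complete linkage, typically on the matrix restricted to the
#' differentially expressed genes from [deGeneFilter()]. Complete linkage
#' guarantees non-decreasing merge heights.
#'
#' @param expr matrix with genes in rows and samples in columns (samples are
#'   clustered).
#' @param genes optional subset of row names to restrict to.
#' @return an object of class \code{\link[stats]{hclust}}.
#' @seealso [dendrogramNewick()] for Newick export.
#' @examples
#' m <- cbind(a = c(0, 0), b = c(1, 0), c = c(10, 0))
#' hc <- hierarchicalCluster(m)
#' hc$height
#' @export
hierarchicalCluster <- function(expr, genes = NULL) {
    stopifnot(is.matrix(expr))
    if (!is.null(genes)) expr <- expr[rownames(expr) %in% genes, ,
                                      drop = FALSE]
    if (ncol(expr) < 2L) stop("at least two samples are required")
    hclust(dist(t(expr), method = "euclidean"), method = "complete")
}

#' Export a dendrogram in Newick format
#'
#' @param hc an \code{hclust} object, e.g. from [hierarchicalCluster()].
#' @param file optional path; when \code{NULL} the Newick string is
#'   returned.
#' @return the Newick string, invisibly when written to a file.
#' @examples
#' hc <- hclust(dist(c(a = 0, b = 1, c = 10)), method = "complete")
#' dendrogramNewick(hc)
#' @export
dendrogramNewick <- function(hc, file = NULL) {
    phy <- ape::as.phylo(hc)
    txt <- ape::write.tree(phy, file = "")
    if (!is.null(file)) {
        writeLines(txt, file)
        return(invisible(txt))
    }
    txt
}

#' Compare enrichment distributions across gene families
#'
#' Summarizes a per-gene quantity (Ago enrichment, log2 ribosome enrichment,
#' binding score, ...) within each family and tests each family against a
#' designated control value set with a two-sided Wilcoxon rank-sum test.
#' Families with fewer than \code{minGenes} measured genes are reported with
#' \code{p = NA}.
#'
#' @param values named numeric vector of per-gene values.
#' @param families named list of gene id vectors.
#' @param control control values: a family name, a gene id vector, or a
#'   numeric vector of values.
#' @param minGenes minimum measured genes per family (default 3).
#' @return data.frame per family with \code{n}, the five-number summary
#'   (\code{min}, \code{q1}, \code{median}, \code{q3}, \code{max}) and
#'   \code{p}.
#' @examples
#' vals <- setNames(c(rnorm(5), rnorm(5, 2)), paste0("g", 1:10))
#' familyEnrichmentCompare(vals,
#'     list(up = paste0("g", 6:10)), control = paste0("g", 1:5))
#' @export
familyEnrichmentCompare <- function(values, families, control,
                                    minGenes = 3L) {
    ctrlValues <- if (is.numeric(control)) {
        control
    } else if (length(control) == 1L && control %in% names(families)) {
        values[intersect(families[[control]], names(values))]
    } else {
        values[intersect(control, names(values))]
    }
    if (length(ctrlValues) < 2L) stop("control set has fewer than 2 values")
    rows <- lapply(names(families), function(f) {
        v <- values[intersect(families[[f]], names(values))]
        fn <- if (length(v)) fivenum(v) else rep(NA_real_, 5L)
        p <- if (length(v) >= minGenes) .rankSumP(v, ctrlValues)
             else NA_real_
        data.frame(family = f, n = length(v), min = fn[1], q1 = fn[2],
                   median = fn[3], q3 = fn[4], max = fn[5], p = p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
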