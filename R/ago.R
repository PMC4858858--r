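#' Quantile normalize an intensity matrix
#'
#' Forces every array (column) to share the same empirical distribution: the
#' row means of the column-wise sorted input. Tied values within a column
#' receive the mean of the reference values at their tied ranks. Applied
#' jointly across all arrays (both channels, all stages) so that
#' Ago/total log2 ratios are computed on a common scale.
#'
#' @param x a numeric matrix of log2 intensities (genes x samples) or a
#'   \linkS4class{SummarizedExperiment} whose first assay holds them.
#' @return An object of the same class with normalized values; with a single
#'   column the input is returned unchanged with a warning.
#'
#' @details The computation is delegated to
#'   \code{\link[limma]{normalizeQuantiles}}.
#' @examples
#' m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
#' quantileNormalize(m)
#' @export
quantileNormalize <- function(x) {
    if (methods::is(x, "SummarizedExperiment")) {
        m <- SummarizedExperiment::assay(x)
        SummarizedExperiment::assay(x) <- quantileNormalize(m)
        return(x)
    }
    if (!is.matrix(x) || !is.numeric(x))
        stop("'x' must be a numeric matrix or SummarizedExperiment")
    if (anyNA(x) || any(!is.finite(x)))
        stop("'x' must not contain missing or non-finite values")
    if (ncol(x) < 2L) {
        warning("single sample: quantile normalization skipped")
        return(x)
    }
    out <- limma::normalizeQuantiles(x, ties = TRUE)
    dimnames(out) <- dimnames(x)
    out
}

# log-likelihood of a two-component Gaussian mixture
.mixLogLik <- function(x, w, mu, sigma) {
    sum(log(w[1] * dnorm(x, mu[1], sigma[1]) +
            w[2] * dnorm(x, mu[2], sigma[2])))
}

# k-means++ seeding in 1-D: first center uniform, second proportional to
# squared distance from the first
.kmeansppCenters <- function(x) {
    c1 <- x[sample.int(length(x), 1L)]
    d2 <- (x - c1)^2
    if (all(d2 == 0)) return(c(c1, c1))
    c2 <- x[sample.int(length(x), 1L, prob = d2)]
    c(c1, c2)
}

#' Fit a two-component Gaussian mixture to log2 intensities
#'
#' EM fit of a background + bound two-component Gaussian mixture to the
#' Ago-channel log2-intensity distribution, which is bimodal when a
#' subpopulation of transcripts is Ago-bound. Components are ordered so that
#' component 1 (the lower mean) is the unbound background; its parameters
#' define the bound-call threshold (see [boundCallThreshold()]).
#'
#' Initialization is k-means++ with two centers on the 1-D values, with
#' \code{nStarts} random restarts; the fit with the best final log-likelihood
#' is kept. The per-iteration log-likelihood is non-decreasing (a standard EM
#' guarantee) and is returned in the \code{logLikTrace} slot. If a component
#' collapses (sigma below \code{sigmaFloor}), the fit restarts from a
#' perturbed initialization; after \code{maxCollapse} collapses an error is
#' raised.
#'
#' @param values numeric vector of finite log2 intensities (>= 100 values
#'   recommended).
#' @param tol convergence tolerance on the log-likelihood increase.
#' @param maxIter maximum EM iterations per start.
#' @param nStarts number of k-means++ restarts.
#' @param seed integer seed controlling the restarts, or \code{NULL}.
#' @param sigmaFloor smallest admissible component sd.
#' @param maxCollapse attempts allowed after degenerate collapses.
#' @return A \linkS4class{MixtureFit}. \code{converged} is \code{FALSE} (not
#'   an error) when \code{maxIter} is reached before \code{tol}.
#'
#' @examples
#' x <- c(rnorm(500, 5, 0.5), rnorm(500, 9, 0.5))
#' fit <- fitBackgroundMixture(x, seed = 1)
#' backgroundMean(fit)
#' @export
fitBackgroundMixture <- function(values, tol = 1e-6, maxIter = 500L,
                                 nStarts = 5L, seed = NULL,
                                 sigmaFloor = 1e-4, maxCollapse = 10L) {
    values <- as.numeric(values)
    if (any(!is.finite(values)))
        stop("'values' must be finite")
    if (length(values) < 10L)
        stop("'values' must contain at least 10 observations")
    if (length(values) < 100L)
        warning("fewer than 100 values: mixture fit may be unstable")

    emOnce <- function(x, mu0) {
        n <- length(x)
        w <- c(0.5, 0.5)
        mu <- sort(mu0)
        sigma <- rep(max(sd(x) / 2, sigmaFloor * 10), 2L)
        ll <- -Inf
        trace <- numeric(0)
        for (it in seq_len(maxIter)) {
            # E step
            d1 <- w[1] * dnorm(x, mu[1], sigma[1])
            d2 <- w[2] * dnorm(x, mu[2], sigma[2])
            tot <- d1 + d2
            tot[tot == 0] <- .Machine$double.xmin
            g <- d1 / tot
            # M step
            n1 <- sum(g); n2 <- n - n1
            if (n1 < 1e-8 || n2 < 1e-8) return(NULL)   # collapsed weight
            mu <- c(sum(g * x) / n1, sum((1 - g) * x) / n2)
            sigma <- sqrt(c(sum(g * (x - mu[1])^2) / n1,
                            sum((1 - g) * (x - mu[2])^2) / n2))
            if (any(!is.finite(sigma)) || any(sigma < sigmaFloor))
                return(NULL)                            # degenerate collapse
            w <- c(n1, n2) / n
            llNew <- .mixLogLik(x, w, mu, sigma)
            trace <- c(trace, llNew)
            if (is.finite(ll) && llNew - ll < tol) {
                ll <- llNew
                return(list(w = w, mu = mu, sigma = sigma, ll = ll,
                            trace = trace, iter = it, converged = TRUE))
            }
            ll <- llNew
        }
        list(w = w, mu = mu, sigma = sigma, ll = ll, trace = trace,
             iter = maxIter, converged = FALSE)
    }

    withSeed(seed, {
        best <- NULL
        collapses <- 0L
        starts <- 0L
        while (starts < nStarts) {
            mu0 <- .kmeansppCenters(values)
            fit <- emOnce(values, mu0)
            if (is.null(fit)) {
                collapses <- collapses + 1L
                if (collapses > maxCollapse)
                    stop("mixture fit collapsed repeatedly (sigma -> 0); ",
                         "data may be degenerate")
                next
            }
            starts <- starts + 1L
            if (is.null(best) || fit$ll > best$ll) best <- fit
        }
        ord <- order(best$mu)
        new("MixtureFit",
            weights = best$w[ord], mu = best$mu[ord], sigma = best$sigma[ord],
            logLik = best$ll, logLikTrace = best$trace,
            nIterations = as.integer(best$iter),
            converged = best$converged)
    })
}

#' Bound-call intensity threshold from a background mixture fit
#'
#' The bound-call cutoff is \code{mu1 + 3 * sigma1}, the mean of the
#' background component plus three of its standard deviations; a pure
#' background gene exceeds it with probability ~0.00135 (0.001 to one
#' significant figure), the accepted false-positive rate of the bound call.
#'
#' @param fit a \linkS4class{MixtureFit}.
#' @return numeric(1), the T1 threshold (log2 intensity units).
#' @examples
#' boundCallThreshold(new("MixtureFit", weights = c(.5, .5), mu = c(5, 9),
#'                        sigma = c(0.5, 0.5), logLik = 0,
#'                        logLikTrace = 0, nIterations = 1L,
#'                        converged = TRUE))  # 6.5
#' @export
boundCallThreshold <- function(fit) {
    stopifnot(methods::is(fit, "MixtureFit"))
    unname(fit@mu[1] + 3 * fit@sigma[1])
}

#' Construct the Ago calling thresholds
#'
#' @param t1 bound-call intensity cutoff, typically from
#'   [boundCallThreshold()].
#' @param t2 enrichment cutoff above which a gene is strongly Ago-enriched.
#' @param t3 cutoff below which a gene is not significantly enriched.
#' @param deltaMin minimum |deltaE| between consecutive stages for a
#'   released/loaded call.
#' @param relaxed if \code{TRUE}, use the relaxed non-enrichment cutoff 1.2
#'   (used downstream for broader gene-set analyses) instead of 0.5.
#' @return An \linkS4class{AgoThresholds}.
#' @examples
#' agoThresholds(t1 = 7.5)
#' agoThresholds(t1 = 7.5, relaxed = TRUE)
#' @export
agoThresholds <- function(t1, t2 = 2, t3 = if (relaxed) 1.2 else 0.5,
                          deltaMin = 1.5, relaxed = FALSE) {
    new("AgoThresholds", t1 = as.numeric(t1), t2 = as.numeric(t2),
        t3 = as.numeric(t3), deltaMin = as.numeric(deltaMin))
}

#' Per-gene, per-stage Ago enrichment
#'
#' Computes, for every gene and stage, the Ago enrichment
#' \code{E = mean(log2 Ago-IP) - mean(log2 total)} (replicates averaged on
#' the log2 scale) and the bound flag \code{mean(log2 Ago-IP) >= T1}. Only
#' genes whose Ago-channel intensity clears the mixture-derived T1 cutoff are
#' considered reliably Ago-bound downstream.
#'
#' @param se a quantile-normalized \linkS4class{SummarizedExperiment} with
#'   colData columns \code{stage} and \code{fraction} (\code{"ago_ip"} /
#'   \code{"total"}); see [simulateArrayExperiment()] for the layout.
#' @param thresholds an \linkS4class{AgoThresholds} (only \code{t1} is used
#'   here).
#' @param stages stages to evaluate, in order; defaults to the order of
#'   appearance in the colData.
#' @return A data.frame with one row per (gene, stage): columns \code{gene},
#'   \code{stage}, \code{E}, \code{agoIntensity}, \code{bound},
#'   \code{assessable}. Stages missing one of the two channels yield
#'   \code{assessable = FALSE} with \code{E = NA}.
#' @examples
#' sim <- simulateArrayExperiment(nGenes = 200, seed = 1)
#' qn <- quantileNormalize(sim$se)
#' fit <- fitBackgroundMixture(
#'     SummarizedExperiment::assay(qn)[, 1], seed = 1)
#' tab <- agoEnrichment(qn, agoThresholds(boundCallThreshold(fit)))
#' head(tab)
#' @export
agoEnrichment <- function(se, thresholds, stages = NULL) {
    stopifnot(methods::is(se, "SummarizedExperiment"),
              methods::is(thresholds, "AgoThresholds"))
    cd <- as.data.frame(SummarizedExperiment::colData(se))
    if (!all(c("stage", "fraction") %in% names(cd)))
        stop("colData must contain 'stage' and 'fraction'")
    m <- SummarizedExperiment::assay(se)
    if (is.null(stages)) stages <- unique(as.character(cd$stage))
    genes <- rownames(m)

    out <- lapply(stages, function(s) {
        agoCols <- which(cd$stage == s & cd$fraction == "ago_ip")
        totCols <- which(cd$stage == s & cd$fraction == "total")
        if (!length(agoCols) || !length(totCols)) {
            return(data.frame(gene = genes, stage = s, E = NA_real_,
                              agoIntensity = NA_real_, bound = NA,
                              assessable = FALSE,
                              stringsAsFactors = FALSE))
        }
        ago <- rowMeans(m[, agoCols, drop = FALSE])
        tot <- rowMeans(m[, totCols, drop = FALSE])
        data.frame(gene = genes, stage = s, E = ago - tot,
                   agoIntensity = ago, bound = ago >= thresholds@t1,
                   assessable = TRUE, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Classify released and loaded genes between consecutive stages
#'
#' For each consecutive stage pair (n, n+1): a gene is \emph{released} from
#' Ago when it is bound at stage n, \code{E_n >= T2}, \code{E_{n+1} <= T3}
#' and \code{|deltaE| >= deltaMin}; it is \emph{loaded} when it is bound at
#' stage n+1, \code{E_n <= T3}, \code{E_{n+1} >= T2} and
#' \code{|deltaE| >= deltaMin} (all inequalities inclusive). Genes failing
#' the bound call at both stages are \code{not_assessed}; everything else is
#' \code{unchanged}.
#'
#' @param table an enrichment table from [agoEnrichment()].
#' @param thresholds an \linkS4class{AgoThresholds}.
#' @param transitions optional character vector like \code{"ES->ELA"}
#'   restricting which adjacent stage pairs to classify; requesting a
#'   non-adjacent pair is an error.
#' @return A data.frame with columns \code{gene}, \code{transition},
#'   \code{deltaE} and \code{call} (factor: released, loaded, unchanged,
#'   not_assessed).
#' @examples
#' sim <- simulateArrayExperiment(nGenes = 500, seed = 1)
#' qn <- quantileNormalize(sim$se)
#' fit <- fitBackgroundMixture(
#'     SummarizedExperiment::assay(qn)[, 1], seed = 1)
#' th <- agoThresholds(boundCallThreshold(fit))
#' calls <- classifyTransitions(agoEnrichment(qn, th), th)
#' table(calls$call)
#' @export
classifyTransitions <- function(table, thresholds, transitions = NULL) {
    stopifnot(is.data.frame(table), methods::is(thresholds, "AgoThresholds"))
    stages <- unique(as.character(table$stage))
    if (length(stages) < 2L)
        stop("at least two stages are required to classify transitions")
    adjacent <- paste0(stages[-length(stages)], "->", stages[-1])
    if (is.null(transitions)) {
        transitions <- adjacent
    } else if (!all(transitions %in% adjacent)) {
        stop("non-adjacent or unknown stage pair requested: ",
             paste(setdiff(transitions, adjacent), collapse = ", "))
    }

    res <- lapply(transitions, function(tr) {
        pair <- strsplit(tr, "->", fixed = TRUE)[[1]]
        a <- table[table$stage == pair[1], ]
        b <- table[table$stage == pair[2], ]
        b <- b[match(a$gene, b$gene), ]
        dE <- b$E - a$E
        released <- a$assessable & b$assessable &
            a$bound & a$E >= thresholds@t2 & b$E <= thresholds@t3 &
            abs(dE) >= thresholds@deltaMin
        loaded <- a$assessable & b$assessable &
            b$bound & a$E <= thresholds@t3 & b$E >= thresholds@t2 &
            abs(dE) >= thresholds@deltaMin
        anyBound <- (a$bound %in% TRUE) | (b$bound %in% TRUE)
        call <- rep("unchanged", nrow(a))
        call[!anyBound | !a$assessable | !b$assessable] <- "not_assessed"
        call[released %in% TRUE] <- "released"
        call[loaded %in% TRUE] <- "loaded"
        data.frame(gene = a$gene, transition = tr, deltaE = dE,
                   call = factor(call, levels = c("released", "loaded",
                                                  "unchanged",
                                                  "not_assessed")),
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    rownames(res) <- NULL
    res
}
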