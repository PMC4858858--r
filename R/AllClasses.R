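#' @import methods
#' @importFrom stats median sd setNames dnorm pnorm rnorm rpois rnbinom runif
#'   binom.test wilcox.test p.adjust t.test pt hclust dist as.dendrogram
#'   quantile fivenum complete.cases kmeans
#' @importFrom utils head write.table read.table combn
#' @useDynLib risctools, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Two-component Gaussian mixture fit
#'
#' Container for an EM fit of a two-component Gaussian mixture to a vector of
#' log2 intensities. Component 1 is the background (unbound) population by
#' convention, so \code{mu(fit)[1] <= mu(fit)[2]}.
#'
#' @slot weights numeric(2), mixing proportions (sum to 1).
#' @slot mu numeric(2), component means in log2 intensity units.
#' @slot sigma numeric(2), component standard deviations (> 0).
#' @slot logLik numeric(1), final observed-data log-likelihood.
#' @slot logLikTrace numeric, per-iteration log-likelihood (non-decreasing).
#' @slot nIterations integer(1), EM iterations run.
#' @slot converged logical(1), whether the tolerance was reached.
#'
#' @seealso [fitBackgroundMixture()], [boundCallThreshold()]
#' @export
setClass("MixtureFit",
    representation(
        weights = "numeric",
        mu = "numeric",
        sigma = "numeric",
        logLik = "numeric",
        logLikTrace = "numeric",
        nIterations = "integer",
        converged = "logical"
    )
)

setValidity("MixtureFit", function(object) {
    msg <- character()
    if (length(object@weights) != 2L || abs(sum(object@weights) - 1) > 1e-9)
        msg <- c(msg, "weights must be two proportions summing to 1")
    if (length(object@mu) != 2L || object@mu[1] > object@mu[2])
        msg <- c(msg, "component means must satisfy mu1 <= mu2")
    if (length(object@sigma) != 2L || any(object@sigma <= 0))
        msg <- c(msg, "component standard deviations must be > 0")
    if (length(msg)) msg else TRUE
})

#' Ago bound-call and transition thresholds
#'
#' Thresholds driving the Ago-RIP calling pipeline: \code{t1} is the
#' bound-call intensity cutoff derived from the background mixture component
#' (mean + 3 sd); \code{t2} is the enrichment level above which a gene counts
#' as strongly Ago-enriched; \code{t3} the level below which it counts as not
#' enriched; \code{deltaMin} the minimum absolute change in enrichment between
#' consecutive stages for a released/loaded call.
#'
#' @slot t1 numeric(1), bound-call log2-intensity cutoff.
#' @slot t2 numeric(1), enrichment cutoff (default 2).
#' @slot t3 numeric(1), non-enrichment cutoff (default 0.5; 1.2 when relaxed).
#' @slot deltaMin numeric(1), minimum |deltaE| (default 1.5).
#'
#' @seealso [agoThresholds()], [classifyTransitions()]
#' @export
setClass("AgoThresholds",
    representation(t1 = "numeric", t2 = "numeric", t3 = "numeric",
                   deltaMin = "numeric")
)

setValidity("AgoThresholds", function(object) {
    msg <- character()
    for (s in c("t1", "t2", "t3", "deltaMin")) {
        v <- slot(object, s)
        if (length(v) != 1L || !is.finite(v))
            msg <- c(msg, sprintf("'%s' must be a single finite number", s))
    }
    if (!length(msg)) {
        if (object@t2 <= object@t3) msg <- c(msg, "t2 must be greater than t3")
        if (object@deltaMin <= 0) msg <- c(msg, "deltaMin must be > 0")
    }
    if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic experiment
#'
#' Records every planted assignment of a synthetic dataset so that downstream
#' calls can be scored against truth: which genes are Ago-bound at each stage,
#' which are released/loaded at each transition, the true per-sample size
#' factors, genes carrying a planted ribosome-occupancy effect, the planted
#' set-D miRNAs, and the planted miRNA binding sites with their UTR offsets.
#'
#' @slot boundGenes list of character vectors, one per stage.
#' @slot releasedGenes list of character vectors, one per transition.
#' @slot loadedGenes list of character vectors, one per transition.
#' @slot effectGenes character, genes with a planted log2 ribosome-enrichment
#'   change.
#' @slot trueSizeFactors numeric, per-sample positive scaling factors.
#' @slot setD character, planted down-regulated ground-state miRNAs.
#' @slot plantedSites data.frame with columns \code{mirna}, \code{gene},
#'   \code{start} (1-based), \code{end}, \code{siteSeq}.
#' @slot targetFamilies character, family names carrying planted sites.
#' @slot seed integer(1), seed the dataset was generated from.
#'
#' @export
setClass("SimTruth",
    representation(
        boundGenes = "list",
        releasedGenes = "list",
        loadedGenes = "list",
        effectGenes = "character",
        trueSizeFactors = "numeric",
        setD = "character",
        plantedSites = "data.frame",
        targetFamilies = "character",
        seed = "integer"
    ),
    prototype(
        boundGenes = list(), releasedGenes = list(), loadedGenes = list(),
        effectGenes = character(), trueSizeFactors = numeric(),
        setD = character(),
        plantedSites = data.frame(mirna = character(), gene = character(),
                                  start = integer(), end = integer(),
                                  siteSeq = character(),
                                  stringsAsFactors = FALSE),
        targetFamilies = character(), seed = NA_integer_
    )
)

setValidity("SimTruth", function(object) {
    msg <- character()
    k <- min(length(object@releasedGenes), length(object@loadedGenes))
    if (k > 0) {
        for (i in seq_len(k)) {
            if (length(intersect(object@releasedGenes[[i]],
                                 object@loadedGenes[[i]])))
                msg <- c(msg, sprintf(
                    "transition %d: released and loaded sets overlap", i))
        }
    }
    if (length(object@trueSizeFactors) && any(object@trueSizeFactors <= 0))
        msg <- c(msg, "all true size factors must be > 0")
    if (length(msg)) msg else TRUE
})
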