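#' @rdname MixtureFit-class
#' @param object,fit a \linkS4class{MixtureFit}.
#' @export
setGeneric("backgroundMean", function(object) standardGeneric("backgroundMean"))

#' @rdname MixtureFit-class
#' @export
setGeneric("backgroundSd", function(object) standardGeneric("backgroundSd"))

#' @rdname MixtureFit-class
#' @export
setGeneric("mixtureWeights", function(object) standardGeneric("mixtureWeights"))

#' @rdname MixtureFit-class
#' @export
setMethod("backgroundMean", "MixtureFit", function(object) object@mu[1])

#' @rdname MixtureFit-class
#' @export
setMethod("backgroundSd", "MixtureFit", function(object) object@sigma[1])

#' @rdname MixtureFit-class
#' @export
setMethod("mixtureWeights", "MixtureFit", function(object) object@weights)

#' @rdname MixtureFit-class
#' @export
setMethod("show", "MixtureFit", function(object) {
    cat("MixtureFit: two-component Gaussian mixture\n")
    cat(sprintf("  background: mu1 = %.4f, sigma1 = %.4f (weight %.3f)\n",
                object@mu[1], object@sigma[1], object@weights[1]))
    cat(sprintf("  bound:      mu2 = %.4f, sigma2 = %.4f (weight %.3f)\n",
                object@mu[2], object@sigma[2], object@weights[2]))
    cat(sprintf("  logLik %.3f after %d iterations (%s)\n", object@logLik,
                object@nIterations,
                if (object@converged) "converged" else "NOT converged"))
    invisible(NULL)
})

#' @rdname AgoThresholds-class
#' @param object an \linkS4class{AgoThresholds}.
#' @export
setMethod("show", "AgoThresholds", function(object) {
    cat("AgoThresholds:\n")
    cat(sprintf("  T1 (bound call)   = %.4f\n", object@t1))
    cat(sprintf("  T2 (enriched)     = %.2f\n", object@t2))
    cat(sprintf("  T3 (not enriched) = %.2f\n", object@t3))
    cat(sprintf("  min |deltaE|      = %.2f\n", object@deltaMin))
    invisible(NULL)
})

#' @rdname SimTruth-class
#' @param object a \linkS4class{SimTruth}.
#' @export
setMethod("show", "SimTruth", function(object) {
    cat("SimTruth (seed", object@seed, ")\n")
    if (length(object@boundGenes))
        cat("  bound per stage:",
            paste(vapply(object@boundGenes, length, 1L), collapse = ", "), "\n")
    if (length(object@releasedGenes))
        cat("  released per transition:",
            paste(vapply(object@releasedGenes, length, 1L), collapse = ", "), "\n")
    if (length(object@loadedGenes))
        cat("  loaded per transition:",
            paste(vapply(object@loadedGenes, length, 1L), collapse = ", "), "\n")
    if (length(object@effectGenes))
        cat("  ribosome-effect genes:", length(object@effectGenes), "\n")
    if (length(object@trueSizeFactors))
        cat("  true size factors:",
            paste(signif(object@trueSizeFactors, 3), collapse = ", "), "\n")
    if (length(object@setD))
        cat("  planted set-D miRNAs:", length(object@setD), "\n")
    if (nrow(object@plantedSites))
        cat("  planted UTR sites:", nrow(object@plantedSites), "in families",
            paste(object@targetFamilies, collapse = ", "), "\n")
    invisible(NULL)
})
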