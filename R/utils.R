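# internal helpers shared across modules

# evaluate `code` under a temporary RNG state seeded with `seed`;
# the caller's RNG stream is untouched
withSeed <- function(seed, code) {
    if (is.null(seed)) return(force(code))
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        stats::runif(1L)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
    force(code)
}

.checkScalar <- function(x, name, min = -Inf, max = Inf, integer = FALSE,
                         strictMin = FALSE) {
    if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
        stop(sprintf("'%s' must be a single finite number", name),
             call. = FALSE)
    if (integer && x != round(x))
        stop(sprintf("'%s' must be an integer", name), call. = FALSE)
    bad <- if (strictMin) x <= min else x < min
    if (bad || x > max)
        stop(sprintf("'%s' must be in %s%s, %s]", name,
                     if (strictMin) "(" else "[", format(min), format(max)),
             call. = FALSE)
    invisible(x)
}

.checkFraction <- function(x, name) .checkScalar(x, name, min = 0, max = 1)

# population (n-denominator) standard deviation by row
.rowSdPop <- function(m) {
    mu <- rowMeans(m)
    sqrt(rowMeans((m - mu)^2))
}

.geneIds <- function(n, prefix = "gene") {
    sprintf("%s_%0*d", prefix, nchar(as.character(n)), seq_len(n))
}

# two-sided rank-sum p-value: exact enumeration of all group assignments
# (tie-aware, matching midranks) when both groups are small, otherwise the
# wilcox.test normal approximation with tie and continuity correction
.rankSumP <- function(x, y, exactMax = 10L) {
    if (length(x) <= exactMax && length(y) <= exactMax) {
        r <- rank(c(x, y))
        n <- length(x)
        W <- sum(r[seq_len(n)])
        combos <- utils::combn(length(r), n)
        sums <- colSums(matrix(r[combos], nrow = n))
        mu <- mean(sums)
        mean(abs(sums - mu) >= abs(W - mu) - 1e-9)
    } else {
        suppressWarnings(
            stats::wilcox.test(x, y, alternative = "two.sided"))$p.value
    }
}

# derive a per-stage seed from a top-level seed, kept under 2^31
deriveSeed <- function(seed, k) {
    as.integer((as.numeric(seed) * 1000 + 97 * k) %% .Machine$integer.max)
}
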