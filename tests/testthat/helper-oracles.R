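# Independent oracles used across the suite. Each re-derives the expected
# quantity from first principles, separately from the package implementation.

# quantile normalization: sort each column, average across columns at each
# rank, then put the averages back in each column's original rank order
# (distinct values only; the tie rule is exercised separately)
oracleQuantileNormalize <- function(m) {
    ref <- rowMeans(apply(m, 2L, sort))
    apply(m, 2L, function(col) ref[rank(col)])
}

# Benjamini-Hochberg by the textbook recipe: sorted p * n / rank, cumulative
# minimum from the largest p down, capped at 1
oracleBH <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    adj <- pmin(adj, 1)
    out <- numeric(n)
    out[o] <- adj
    out
}

# exact two-sided rank-sum p by full enumeration of all group assignments
oracleRankSumP <- function(x, y) {
    ranks <- rank(c(x, y))
    n <- length(x)
    W <- sum(ranks[seq_len(n)])
    combos <- utils::combn(length(x) + length(y), n)
    stats <- apply(combos, 2L, function(idx) sum(ranks[idx]))
    mu <- mean(stats)
    mean(abs(stats - mu) >= abs(W - mu) - 1e-9)
}

# exhaustive (memoized top-down) best local alignment of a miRNA against a
# short UTR window under the same scoring model as the aligner: reversed
# miRNA, complementarity scoring with G:U wobble, seed positions up-weighted,
# affine gaps
oracleDuplexScore <- function(mirna, utr, p = duplexParams()) {
    q <- rev(strsplit(chartr("Uu", "Tt", toupper(mirna)), "")[[1]])
    tt <- strsplit(chartr("Uu", "Tt", toupper(utr)), "")[[1]]
    m <- length(q); n <- length(tt)
    pairScore <- function(i, j) {
        ab <- paste(sort(c(q[i], tt[j])), collapse = "")
        s <- if (ab %in% c("AT", "CG")) p$matchScore
             else if (ab == "GT") p$wobbleScore
             else p$mismatchScore
        pos5 <- m - i + 1
        if (pos5 >= p$seedStart && pos5 <= p$seedEnd) s * p$seedWeight else s
    }
    memo <- new.env(hash = TRUE)
    rec <- function(i, j, state) {
        if (i < 1 || j < 1) return(-Inf)
        key <- paste(i, j, state)
        if (!is.null(memo[[key]])) return(memo[[key]])
        val <- if (state == "M") {
            best <- max(0,
                        rec(i - 1, j - 1, "M"),
                        rec(i - 1, j - 1, "X"),
                        rec(i - 1, j - 1, "Y"))
            best + pairScore(i, j)
        } else if (state == "X") {
            max(rec(i - 1, j, "M") + p$gapOpen,
                rec(i - 1, j, "X") + p$gapExt)
        } else {
            max(rec(i, j - 1, "M") + p$gapOpen,
                rec(i, j - 1, "Y") + p$gapExt)
        }
        memo[[key]] <- val
        val
    }
    best <- 0
    for (i in seq_len(m)) for (j in seq_len(n))
        best <- max(best, rec(i, j, "M"))
    best
}

# reverse complement returning a plain DNA character string
rcDNA <- function(x) {
    x <- chartr("Uu", "Tt", x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

randomSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
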