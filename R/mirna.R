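#' Reads-per-million normalization
#'
#' @param counts non-negative matrix of small-RNA counts (miRNAs x samples).
#' @param librarySizes total mapped reads per sample (strictly positive),
#'   recycled and name-matched to columns when named.
#' @return matrix of RPM values: \code{count / (librarySize / 1e6)}.
#' @examples
#' rpmNormalize(cbind(s1 = c(5, 0)), librarySizes = 2e6)  # 2.5, 0
#' @export
rpmNormalize <- function(counts, librarySizes) {
    if (!is.matrix(counts)) counts <- as.matrix(counts)
    librarySizes <- rep_len(librarySizes, ncol(counts))
    if (any(!is.finite(librarySizes)) || any(librarySizes <= 0))
        stop("'librarySizes' must be strictly positive")
    sweep(counts, 2L, librarySizes / 1e6, "/")
}

#' Select the down-regulated ground-state miRNA set ("set D")
#'
#' Flags the miRNAs whose mean log2 RPM across a reference/test condition
#' pair is at least \code{minMean} and whose log2 fold change (test vs
#' reference) is at most \code{maxFc} (both inclusive). Logs use a +1
#' pseudocount: \code{log2(RPM + pseudocount)}.
#'
#' @param rpm matrix of RPM values (miRNAs x conditions).
#' @param refCondition,testCondition column names of the compared pair
#'   (defaults: \code{"ES"}, \code{"ELA"}).
#' @param minMean inclusive lower bound on mean log2 RPM (default 5).
#' @param maxFc inclusive upper bound on log2 fold change (default -1).
#' @param pseudocount added before taking log2 (default 1).
#' @return data.frame per miRNA with \code{meanLog2Rpm}, \code{log2Fc},
#'   \code{inSetD}; the selected ids are
#'   \code{rownames(rpm)[out$inSetD]}.
#' @examples
#' rpm <- cbind(ES = c(300, 20), ELA = c(60, 20))
#' rownames(rpm) <- c("mirA", "mirB")
#' selectSetD(rpm)
#' @export
selectSetD <- function(rpm, refCondition = "ES", testCondition = "ELA",
                       minMean = 5, maxFc = -1, pseudocount = 1) {
    if (!all(c(refCondition, testCondition) %in% colnames(rpm)))
        stop("'rpm' must have columns '", refCondition, "' and '",
             testCondition, "'")
    lRef <- log2(rpm[, refCondition] + pseudocount)
    lTest <- log2(rpm[, testCondition] + pseudocount)
    meanLog2Rpm <- (lRef + lTest) / 2
    log2Fc <- lTest - lRef
    data.frame(mirna = rownames(rpm), meanLog2Rpm = meanLog2Rpm,
               log2Fc = log2Fc,
               inSetD = meanLog2Rpm >= minMean & log2Fc <= maxFc,
               row.names = rownames(rpm), stringsAsFactors = FALSE)
}

#' Duplex alignment scoring parameters
#'
#' Defaults mirror published miRanda-class settings: +5 for a Watson-Crick
#' pair, +1 for a G:U wobble, -3 for a mismatch, affine gaps (-9 open, -4
#' extend), and substitution scores at miRNA positions 2-8 (the seed) scaled
#' by 4. The duplex free energy is a per-pair sum (G:C -2.2, A:U -1.1, G:U
#' -0.5 kcal/mol over paired positions), a deterministic proxy that is
#' monotone in pairing extent. A hit passes when \code{score >= minScore} and
#' \code{energy <= maxEnergy}.
#'
#' @param matchScore,wobbleScore,mismatchScore substitution scores.
#' @param gapOpen,gapExt affine gap penalties (negative).
#' @param seedStart,seedEnd,seedWeight seed window (miRNA 5'-based positions)
#'   and its score multiplier.
#' @param energyGC,energyAU,energyGU per-pair energies, kcal/mol.
#' @param minScore,maxEnergy pass thresholds (defaults 140 and -10 kcal/mol).
#' @param reportMin do not report local alignments scoring below this
#'   (default: the pass threshold \code{minScore}; lower it to inspect
#'   sub-threshold hits).
#' @param maxHits maximal non-overlapping hits reported per (miRNA, UTR).
#' @return a named list of class \code{"duplexParams"}.
#' @examples
#' duplexParams(minScore = 120)
#' @export
duplexParams <- function(matchScore = 5, wobbleScore = 1, mismatchScore = -3,
                         gapOpen = -9, gapExt = -4,
                         seedStart = 2, seedEnd = 8, seedWeight = 4,
                         energyGC = -2.2, energyAU = -1.1, energyGU = -0.5,
                         minScore = 140, maxEnergy = -10,
                         reportMin = minScore, maxHits = 8L) {
    p <- list(matchScore = matchScore, wobbleScore = wobbleScore,
              mismatchScore = mismatchScore, gapOpen = gapOpen,
              gapExt = gapExt, seedStart = as.integer(seedStart),
              seedEnd = as.integer(seedEnd), seedWeight = seedWeight,
              energyGC = energyGC, energyAU = energyAU, energyGU = energyGU,
              minScore = minScore, maxEnergy = maxEnergy,
              reportMin = reportMin, maxHits = as.integer(maxHits))
    if (p$seedStart < 1L || p$seedEnd < p$seedStart)
        stop("'seedStart'/'seedEnd' must satisfy 1 <= seedStart <= seedEnd")
    class(p) <- "duplexParams"
    p
}

.validSeq <- function(x, name) {
    x <- toupper(as.character(x))
    if (!grepl("^[ACGTU]+$", x))
        stop(sprintf("'%s' contains characters outside the A/C/G/T/U alphabet",
                     name))
    x
}

#' Align one miRNA against one 3'UTR
#'
#' Seed-weighted affine-gap local alignment of the miRNA (antiparallel, so
#' "match" means Watson-Crick or G:U complementarity) against the UTR, in the
#' style of miRanda-class target scanners. Non-overlapping hits are reported
#' greedily by descending score; each carries an alignment score, a summed
#' per-pair free-energy estimate and a \code{passes} flag (score and energy
#' thresholds jointly satisfied).
#'
#' @param mirna miRNA sequence, 5'->3' (character or XString; U and T are
#'   equivalent).
#' @param utr 3'UTR sequence, 5'->3'.
#' @param params a [duplexParams()] list.
#' @return data.frame of hits: \code{score}, \code{utrStart}/\code{utrEnd}
#'   (1-based, inclusive), \code{mirnaStart}/\code{mirnaEnd} (5'-based miRNA
#'   positions), \code{energy} (kcal/mol), \code{nPairs}, \code{passes}.
#' @examples
#' mir <- "UAAGGCACGCGGUGAAUGCCAA"
#' utr <- paste0(strrep("A", 30),
#'               as.character(Biostrings::reverseComplement(
#'                   Biostrings::DNAString(chartr("U", "T", mir)))),
#'               strrep("A", 30))
#' alignDuplex(mir, utr)
#' @export
alignDuplex <- function(mirna, utr, params = duplexParams()) {
    m <- chartr("U", "T", .validSeq(mirna, "mirna"))
    u <- chartr("U", "T", .validSeq(utr, "utr"))
    hits <- .duplex_align_cpp(m, u,
        params$matchScore, params$wobbleScore, params$mismatchScore,
        params$gapOpen, params$gapExt,
        params$seedStart, params$seedEnd, params$seedWeight,
        params$energyGC, params$energyAU, params$energyGU,
        params$reportMin, params$maxHits)
    hits$passes <- hits$score >= params$minScore &
        hits$energy <= params$maxEnergy
    hits
}

#' Scan a miRNA set against a UTR set
#'
#' Runs [alignDuplex()] for every (miRNA, UTR) pair and binds the hit tables,
#' adding \code{mirna} and \code{gene} columns.
#'
#' @param mirnas named character vector or \code{RNAStringSet}/
#'   \code{DNAStringSet} of mature miRNA sequences.
#' @param utrs named character vector or \code{DNAStringSet} of 3'UTRs.
#' @param params a [duplexParams()] list.
#' @return data.frame of hits across all pairs (possibly zero rows).
#' @examples
#' sim <- simulateMirnaAndUtrs(nMirnas = 10, genesPerFamily = 2,
#'                             nBackgroundGenes = 2, seed = 1)
#' hits <- scanDuplexes(sim$mirnas[sim$truth@setD], sim$utrs[1:4])
#' head(hits)
#' @export
scanDuplexes <- function(mirnas, utrs, params = duplexParams()) {
    mirnas <- vapply(as.character(mirnas), identity, "")
    utrs <- vapply(as.character(utrs), identity, "")
    if (is.null(names(mirnas)) || is.null(names(utrs)))
        stop("'mirnas' and 'utrs' must be named")
    out <- vector("list", length(mirnas) * length(utrs))
    k <- 0L
    for (mi in names(mirnas)) {
        for (gi in names(utrs)) {
            h <- alignDuplex(mirnas[[mi]], utrs[[gi]], params)
            if (nrow(h)) {
                k <- k + 1L
                out[[k]] <- cbind(mirna = mi, gene = gi, h,
                                  stringsAsFactors = FALSE)
            }
        }
    }
    if (k == 0L)
        return(data.frame(mirna = character(), gene = character(),
                          score = numeric(), utrStart = integer(),
                          utrEnd = integer(), mirnaStart = integer(),
                          mirnaEnd = integer(), energy = numeric(),
                          nPairs = integer(), passes = logical(),
                          stringsAsFactors = FALSE))
    res <- do.call(rbind, out[seq_len(k)])
    rownames(res) <- NULL
    res
}

#' Cumulative per-gene binding score
#'
#' Sums the scores of passing hits of the selected miRNAs (typically set D)
#' over each gene's 3'UTR; genes without passing hits score 0.
#'
#' @param hits hit table from [scanDuplexes()].
#' @param mirnaSet miRNA ids to include, or \code{NULL} for all.
#' @param genes gene universe defining the output (genes without hits get 0);
#'   defaults to the genes present in \code{hits}.
#' @param families optional named list of gene id vectors; adds a
#'   \code{family} column (\code{NA} for unannotated genes).
#' @return data.frame with \code{gene}, \code{score} and optionally
#'   \code{family}.
#' @examples
#' hits <- data.frame(mirna = "m1", gene = c("g1", "g1", "g2"),
#'                    score = c(150, 160, 150),
#'                    energy = c(-12, -15, -8),
#'                    passes = c(TRUE, TRUE, FALSE))
#' cumulativeBindingScore(hits, genes = c("g1", "g2", "g3"))
#' @export
cumulativeBindingScore <- function(hits, mirnaSet = NULL, genes = NULL,
                                   families = NULL) {
    h <- hits[hits$passes %in% TRUE, , drop = FALSE]
    if (!is.null(mirnaSet)) h <- h[h$mirna %in% mirnaSet, , drop = FALSE]
    if (is.null(genes)) genes <- unique(hits$gene)
    score <- setNames(numeric(length(genes)), genes)
    if (nrow(h)) {
        s <- tapply(h$score, h$gene, sum)
        score[names(s)] <- s
    }
    out <- data.frame(gene = genes, score = unname(score),
                      stringsAsFactors = FALSE)
    if (!is.null(families)) {
        fam <- rep(NA_character_, length(genes))
        for (f in names(families))
            fam[genes %in% families[[f]]] <- f
        out$family <- fam
    }
    out
}

#' Scramble UTR sequences
#'
#' Replaces every sequence by a uniform random permutation of its own
#' letters, preserving length and mononucleotide composition exactly; the
#' standard null model for binding-site content.
#'
#' @param utrs named character vector or \code{DNAStringSet}.
#' @param seed integer seed, or \code{NULL}.
#' @return object of the same type with scrambled sequences.
#' @examples
#' scrambleUtrs(c(g1 = "ACGTACGT"), seed = 1)
#' @export
scrambleUtrs <- function(utrs, seed = NULL) {
    isXSS <- methods::is(utrs, "XStringSet")
    seqs <- as.character(utrs)
    withSeed(seed, {
        scr <- vapply(seqs, function(s) {
            paste(sample(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
        }, "")
    })
    names(scr) <- names(utrs)
    if (isXSS) Biostrings::DNAStringSet(scr) else scr
}

#' Rank-sum test of family binding scores against a null
#'
#' Compares each gene family's cumulative binding-score distribution to a
#' null score distribution (scores of a random gene set, or of the same
#' genes on scrambled UTRs) with a two-sided Wilcoxon rank-sum test. The
#' p-value is computed by exact enumeration when both groups have at most 10
#' values, otherwise by the normal approximation with tie and continuity
#' correction.
#'
#' @param scores data.frame from [cumulativeBindingScore()] with a
#'   \code{family} column, or a named numeric vector of per-gene scores
#'   combined with \code{families}.
#' @param families named list of gene id vectors (ignored when \code{scores}
#'   already carries a \code{family} column).
#' @param nullScores numeric vector of null scores.
#' @param minGenes families with fewer scored genes are skipped with a
#'   warning (default 3).
#' @return data.frame per family: \code{n}, \code{median},
#'   \code{nullMedian}, \code{p}.
#' @examples
#' sc <- c(a1 = 300, a2 = 310, a3 = 320)
#' familyBindingTest(sc, families = list(A = names(sc)),
#'                   nullScores = c(0, 0, 5))
#' @export
familyBindingTest <- function(scores, families = NULL, nullScores,
                              minGenes = 3L) {
    if (is.data.frame(scores)) {
        stopifnot("family" %in% names(scores))
        values <- setNames(scores$score, scores$gene)
        families <- split(scores$gene[!is.na(scores$family)],
                          scores$family[!is.na(scores$family)])
    } else {
        values <- scores
        if (is.null(families)) stop("'families' is required")
    }
    rows <- lapply(names(families), function(f) {
        v <- values[intersect(families[[f]], names(values))]
        if (length(v) < minGenes) {
            warning("family '", f, "' has fewer than ", minGenes,
                    " scored genes; skipped")
            return(NULL)
        }
        p <- .rankSumP(v, nullScores)
        data.frame(family = f, n = length(v), median = median(v),
                   nullMedian = median(nullScores), p = p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(family = character(), n = integer(),
                          median = numeric(), nullMedian = numeric(),
                          p = numeric(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Row-wise expression z-scores across conditions
#'
#' Standardizes each miRNA's expression across conditions:
#' \code{z = (x - rowMean) / rowSd} with the population (n-denominator)
#' standard deviation; rows with zero sd map to all-zero z-scores.
#'
#' @param x matrix of expression values (miRNAs x conditions, >= 2 columns).
#' @return matrix of z-scores with the same dimnames.
#' @examples
#' mirnaZScores(rbind(c(0, 0, 10, 10), c(7, 7, 7, 7)))
#' @export
mirnaZScores <- function(x) {
    if (!is.matrix(x)) x <- as.matrix(x)
    if (ncol(x) < 2L) stop("at least two conditions are required")
    mu <- rowMeans(x)
    sdp <- .rowSdPop(x)
    z <- (x - mu) / ifelse(sdp > 0, sdp, 1)
    z[sdp == 0, ] <- 0
    z
}
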