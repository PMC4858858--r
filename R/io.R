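#' Read a gene-by-sample TSV matrix
#'
#' Expects a tab-separated file whose first column holds gene (or miRNA) ids
#' and whose remaining named columns hold one sample each.
#'
#' @param path file path.
#' @return numeric matrix with gene ids as row names.
#' @export
readMatrixTSV <- function(path) {
    df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                     stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    storage.mode(m) <- "double"
    m
}

#' Write a gene-by-sample matrix as TSV
#'
#' @param m matrix with row names.
#' @param path output path.
#' @param idColumn name of the id column (default \code{"gene"}).
#' @export
writeMatrixTSV <- function(m, path, idColumn = "gene") {
    df <- data.frame(rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1] <- idColumn
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read sample metadata TSV
#'
#' One row per sample; the first column is the sample name, remaining
#' columns annotate it (stage/condition, fraction, replicate).
#'
#' @param path file path.
#' @return data.frame with sample names as row names.
#' @export
readSampleMetadata <- function(path) {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    rownames(df) <- df[[1]]
    df
}

#' Read gene sets in GMT format
#'
#' Tab-separated: set name, description, then member gene ids.
#'
#' @param path file path.
#' @return named list of character vectors (empty sets dropped with a
#'   warning).
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sets <- lapply(lines, function(l) {
        parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
        members <- parts[-(1:2)]
        members[nzchar(members)]
    })
    names(sets) <- vapply(lines, function(l)
        strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
    empty <- lengths(sets) == 0L
    if (any(empty)) {
        warning("empty gene sets skipped: ",
                paste(names(sets)[empty], collapse = ", "))
        sets <- sets[!empty]
    }
    sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
writeGmt <- function(sets, path) {
    lines <- vapply(names(sets), function(n)
        paste(c(n, "na", sets[[n]]), collapse = "\t"), "")
    writeLines(lines, path)
    invisible(path)
}

#' Write a simulation ground truth as JSON
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param path output path.
#' @export
writeTruthJSON <- function(truth, path) {
    stopifnot(methods::is(truth, "SimTruth"))
    obj <- list(
        boundGenes = truth@boundGenes,
        releasedGenes = truth@releasedGenes,
        loadedGenes = truth@loadedGenes,
        effectGenes = truth@effectGenes,
        trueSizeFactors = as.list(truth@trueSizeFactors),
        setD = truth@setD,
        plantedSites = truth@plantedSites,
        targetFamilies = truth@targetFamilies,
        seed = truth@seed)
    jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
    invisible(path)
}

#' Validate matrix, metadata, FASTA and GMT inputs
#'
#' Structural checks run before a pipeline: sample metadata must agree with
#' matrix column names (fatal otherwise); FASTA sequences must use the
#' A/C/G/T/U alphabet (lowercase accepted with a warning); GMT member genes
#' should be resolvable in the supplied gene universe (warning otherwise).
#'
#' @param matrix optional numeric matrix with sample columns.
#' @param metadata optional data.frame whose row (or first-column) names are
#'   sample names.
#' @param sequences optional named character vector / XStringSet.
#' @param geneSets optional named list of gene id vectors.
#' @param geneUniverse optional character vector used to resolve gene-set
#'   members.
#' @return list with character vectors \code{errors} and \code{warnings};
#'   \code{ok} is \code{TRUE} when no fatal error was found.
#' @examples
#' validateInputs(matrix = cbind(s1 = 1:3),
#'                metadata = data.frame(sample = "s1"))
#' @export
validateInputs <- function(matrix = NULL, metadata = NULL, sequences = NULL,
                           geneSets = NULL, geneUniverse = NULL) {
    errors <- warnings <- character()
    if (!is.null(matrix) && !is.null(metadata)) {
        metaSamples <- if (!is.null(rownames(metadata)) &&
                           !all(rownames(metadata) == seq_len(nrow(metadata))))
            rownames(metadata) else as.character(metadata[[1]])
        missing <- setdiff(metaSamples, colnames(matrix))
        if (length(missing))
            errors <- c(errors, paste0(
                "metadata sample(s) absent from matrix columns: ",
                paste(missing, collapse = ", ")))
        extra <- setdiff(colnames(matrix), metaSamples)
        if (length(extra))
            warnings <- c(warnings, paste0(
                "matrix column(s) without metadata: ",
                paste(extra, collapse = ", ")))
    }
    if (!is.null(sequences)) {
        seqs <- as.character(sequences)
        if (any(grepl("[a-z]", seqs)))
            warnings <- c(warnings,
                          "lowercase letters in sequences; canonicalized")
        bad <- grepl("[^ACGTUacgtu]", seqs)
        if (any(bad))
            errors <- c(errors, paste0(
                "invalid sequence alphabet in: ",
                paste(utils::head(names(seqs)[bad], 5L), collapse = ", ")))
    }
    if (!is.null(geneSets)) {
        empty <- lengths(geneSets) == 0L
        if (any(empty))
            warnings <- c(warnings, paste0(
                "empty gene set(s): ",
                paste(names(geneSets)[empty], collapse = ", ")))
        if (!is.null(geneUniverse)) {
            unresolved <- vapply(geneSets, function(s)
                sum(!s %in% geneUniverse), 0)
            if (any(unresolved > 0))
                warnings <- c(warnings, paste0(
                    "gene set member(s) not in universe: ",
                    paste(names(geneSets)[unresolved > 0], collapse = ", ")))
        }
    }
    list(ok = length(errors) == 0L, errors = errors, warnings = warnings)
}
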