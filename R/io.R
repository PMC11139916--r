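## Table reading, validation, alignment and result writing.

#' @keywords internal
#' @noRd
.detectSep <- function(path) {
    line <- readLines(path, n = 1L)
    if (grepl("\t", line)) "\t" else ","
}

#' Validate a count matrix
#'
#' Checks non-negativity, integrality (no silent rounding) and unique
#' taxon/sample identifiers; errors name the offending cell.
#'
#' @param counts numeric matrix, taxa x samples, with dimnames.
#' @return the validated matrix with integer storage.
#' @export
validateCounts <- function(counts) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("count matrix must have taxon row names and sample column names")
    if (anyDuplicated(rownames(counts)))
        stop("duplicated taxon ids: ",
             paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                   collapse = ", "))
    if (anyDuplicated(colnames(counts)))
        stop("duplicated sample ids: ",
             paste(unique(colnames(counts)[duplicated(colnames(counts))]),
                   collapse = ", "))
    if (!is.numeric(counts) || any(is.na(counts))) {
        bad <- which(is.na(suppressWarnings(matrix(as.numeric(counts),
                                                   nrow = nrow(counts)))),
                     arr.ind = TRUE)[1, , drop = TRUE]
        stop(sprintf("non-numeric count at taxon '%s', sample '%s'",
                     rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
    }
    if (any(counts < 0)) {
        bad <- which(counts < 0, arr.ind = TRUE)[1, ]
        stop(sprintf("negative count (%g) at taxon '%s', sample '%s'",
                     counts[bad[1], bad[2]],
                     rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
    }
    if (any(counts != floor(counts))) {
        bad <- which(counts != floor(counts), arr.ind = TRUE)[1, ]
        stop(sprintf(
            "non-integer count (%g) at taxon '%s', sample '%s'; counts must be integers",
            counts[bad[1], bad[2]],
            rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
    }
    storage.mode(counts) <- "integer"
    counts
}

#' Read a taxa-by-samples count table
#'
#' Reads a TSV/CSV with a header row and an id column, validates the
#' entries (integers >= 0, unique ids) and normalizes the orientation to
#' taxa x samples.
#'
#' @param path file path.
#' @param orientation \code{"taxa_rows"} (default) if rows are taxa,
#'   \code{"samples_rows"} if rows are samples (the table is transposed).
#' @param sep field separator; auto-detected (tab, else comma) when
#'   \code{NULL}.
#' @return validated integer matrix, taxa x samples.
#' @export
readCountTable <- function(path, orientation = c("taxa_rows", "samples_rows"),
                           sep = NULL) {
    orientation <- match.arg(orientation)
    if (!file.exists(path)) stop("file not found: ", path)
    if (is.null(sep)) sep <- .detectSep(path)
    df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                     row.names = 1L, colClasses = "character",
                     comment.char = "")
    m <- matrix(suppressWarnings(as.numeric(as.matrix(df))),
                nrow = nrow(df), dimnames = dimnames(df))
    if (any(is.na(m))) {
        bad <- which(is.na(m), arr.ind = TRUE)[1, ]
        stop(sprintf("non-numeric count '%s' at row '%s', column '%s'",
                     as.matrix(df)[bad[1], bad[2]],
                     rownames(m)[bad[1]], colnames(m)[bad[2]]))
    }
    if (orientation == "samples_rows") m <- t(m)
    validateCounts(m)
}

#' Read a sample metadata table
#'
#' First column (or row names) holds sample ids; remaining columns are
#' treated as categorical factors.
#'
#' @inheritParams readCountTable
#' @return \code{data.frame} with sample ids as row names and factor
#'   columns.
#' @export
readSampleMetadata <- function(path, sep = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (is.null(sep)) sep <- .detectSep(path)
    df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                     row.names = 1L, stringsAsFactors = FALSE)
    if (anyDuplicated(rownames(df)))
        stop("duplicated sample ids in metadata")
    for (cn in colnames(df)) df[[cn]] <- factor(df[[cn]])
    df
}

#' Read a taxonomy table
#'
#' First column (or row names) holds taxon ids; remaining columns are
#' lineage ranks (kingdom ... species; partial lineages allowed).
#'
#' @inheritParams readCountTable
#' @return \code{data.frame} with taxon ids as row names.
#' @export
readTaxonomyTable <- function(path, sep = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (is.null(sep)) sep <- .detectSep(path)
    df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                     row.names = 1L, stringsAsFactors = FALSE)
    if (anyDuplicated(rownames(df)))
        stop("duplicated taxon ids in taxonomy")
    df
}

#' Align count, metadata and taxonomy tables
#'
#' Restricts samples to the intersection of count columns and metadata
#' rows (order taken from the count table) and, when a taxonomy is given,
#' taxa to the intersection with taxonomy rows. Aligning an already
#' aligned triple is the identity.
#'
#' @param counts taxa x samples count matrix.
#' @param meta sample metadata \code{data.frame} (row names = sample ids).
#' @param taxonomy optional taxonomy \code{data.frame} (row names = taxon
#'   ids).
#' @return list with elements \code{counts}, \code{meta}, \code{taxonomy}
#'   and \code{dropped} (a list of dropped sample/taxon ids per table).
#' @export
alignTables <- function(counts, meta, taxonomy = NULL) {
    samples <- intersect(colnames(counts), rownames(meta))
    if (length(samples) == 0L)
        stop("no samples shared between count table and metadata")
    samples <- colnames(counts)[colnames(counts) %in% samples]
    dropped <- list(
        samples_counts = setdiff(colnames(counts), samples),
        samples_meta = setdiff(rownames(meta), samples))
    counts <- counts[, samples, drop = FALSE]
    meta <- meta[samples, , drop = FALSE]
    if (!is.null(taxonomy)) {
        taxa <- rownames(counts)[rownames(counts) %in% rownames(taxonomy)]
        if (length(taxa) == 0L)
            stop("no taxa shared between count table and taxonomy")
        dropped$taxa_counts <- setdiff(rownames(counts), taxa)
        dropped$taxa_taxonomy <- setdiff(rownames(taxonomy), taxa)
        counts <- counts[taxa, , drop = FALSE]
        taxonomy <- taxonomy[taxa, , drop = FALSE]
    }
    list(counts = counts, meta = meta, taxonomy = taxonomy,
         dropped = dropped)
}

#' Write a differential abundance result table
#'
#' Writes a TSV with the fixed column order \code{taxon_id, base_mean,
#' log2fc, stat, df, pvalue, padj, structured_zero, path}; numeric values
#' are written with 10 significant digits so a read-back reproduces them.
#'
#' @param results a \linkS4class{DAResults} (or coercible data.frame).
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeResults <- function(results, path) {
    if (!is(results, "DAResults")) results <- DAResults(results)
    df <- as.data.frame(results)[, .daCols, drop = FALSE]
    for (cn in c("base_mean", "log2fc", "stat", "pvalue", "padj"))
        df[[cn]] <- formatC(df[[cn]], digits = 10, format = "g")
    con <- tryCatch(suppressWarnings(file(path, "w")),
                    error = function(e)
        stop("cannot write to ", path, ": ", conditionMessage(e)))
    on.exit(close(con))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read back a result table written by [writeResults()]
#'
#' @param path file path.
#' @return a \linkS4class{DAResults}.
#' @export
readResults <- function(path) {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE,
                     colClasses = c(taxon_id = "character"))
    df$structured_zero <- as.logical(df$structured_zero)
    DAResults(df)
}
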