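#' Container for a taxa-by-samples microbiome count experiment
#'
#' Extends \linkS4class{SummarizedExperiment}. The \code{"counts"} assay
#' holds non-negative integer counts with taxa as rows and samples as
#' columns; \code{colData} carries the sample metadata factors and
#' \code{rowData} an optional taxonomy.
#'
#' @slot ... inherited from \linkS4class{SummarizedExperiment}.
#' @aliases MicrobExperiment-class
#' @exportClass MicrobExperiment
setClass("MicrobExperiment", contains = "SummarizedExperiment")

.validMicrobExperiment <- function(object) {
    msg <- NULL
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        m <- assay(object, "counts")
        if (is.null(rownames(m)) || is.null(colnames(m)))
            msg <- c(msg, "counts must have taxon row names and sample column names")
        else {
            if (anyDuplicated(rownames(m)))
                msg <- c(msg, "duplicated taxon ids")
            if (anyDuplicated(colnames(m)))
                msg <- c(msg, "duplicated sample ids")
        }
        if (any(is.na(m)))
            msg <- c(msg, "counts contain missing values")
        else {
            if (any(m < 0))
                msg <- c(msg, "counts contain negative entries")
            if (any(m != floor(m)))
                msg <- c(msg, "counts contain non-integer entries")
        }
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("MicrobExperiment", .validMicrobExperiment)

#' Construct a MicrobExperiment
#'
#' @param counts non-negative integer matrix, taxa in rows, samples in
#'   columns, with unique dimnames.
#' @param sampleData \code{data.frame} of per-sample covariates, row names
#'   matching the count columns (reordered if necessary).
#' @param taxonomy optional \code{data.frame} of per-taxon lineage, row
#'   names matching the count rows.
#' @return a \linkS4class{MicrobExperiment}.
#' @examples
#' m <- matrix(c(0L, 3L, 5L, 2L, 0L, 7L), nrow = 2,
#'             dimnames = list(c("t1", "t2"), c("s1", "s2", "s3")))
#' me <- MicrobExperiment(m, data.frame(group = c("a", "a", "b"),
#'                                      row.names = colnames(m)))
#' @export
MicrobExperiment <- function(counts, sampleData = NULL, taxonomy = NULL) {
    counts <- validateCounts(counts)
    args <- list(assays = list(counts = counts))
    if (!is.null(sampleData)) {
        if (!all(colnames(counts) %in% rownames(sampleData)))
            stop("sampleData is missing samples: ",
                 paste(setdiff(colnames(counts), rownames(sampleData)),
                       collapse = ", "))
        args$colData <- DataFrame(sampleData[colnames(counts), , drop = FALSE])
    }
    if (!is.null(taxonomy)) {
        rd <- DataFrame(row.names = rownames(counts))
        hit <- intersect(rownames(counts), rownames(taxonomy))
        for (cn in colnames(taxonomy)) {
            rd[[cn]] <- NA_character_
            rd[hit, cn] <- as.character(taxonomy[hit, cn])
        }
        args$rowData <- rd
    }
    se <- do.call(SummarizedExperiment, args)
    new("MicrobExperiment", se)
}

#' @describeIn MicrobExperiment count matrix accessor.
#' @param object a \code{MicrobExperiment}.
#' @export
setMethod("counts", "MicrobExperiment", function(object) {
    assay(object, "counts")
})

setMethod("show", "MicrobExperiment", function(object) {
    m <- assay(object, "counts")
    cat("MicrobExperiment:", nrow(m), "taxa x", ncol(m), "samples\n")
    cat(sprintf("zero fraction: %.3f\n", mean(m == 0)))
    callNextMethod()
})

#' Per-sample size factors
#'
#' Positive scale factors, rescaled so their geometric mean is 1, used as
#' log offsets in the negative binomial models.
#'
#' @slot s named positive numeric vector of per-sample factors.
#' @slot method scheme used: \code{"poscounts"}, \code{"tmm"} or
#'   \code{"gmpr"}.
#' @aliases SizeFactors-class
#' @exportClass SizeFactors
setClass("SizeFactors",
         representation(s = "numeric", method = "character"))

setValidity("SizeFactors", function(object) {
    msg <- NULL
    if (any(!is.finite(object@s)) || any(object@s <= 0))
        msg <- c(msg, "size factors must be positive and finite")
    if (is.null(names(object@s)))
        msg <- c(msg, "size factors must be named by sample")
    gm <- exp(mean(log(object@s)))
    if (is.finite(gm) && abs(gm - 1) > 1e-6)
        msg <- c(msg, "size factors must have geometric mean 1")
    if (length(object@method) != 1L)
        msg <- c(msg, "method must be a single string")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn SizeFactors numeric values accessor.
#' @param x a \code{SizeFactors} object.
#' @export
sfValues <- function(x) x@s

#' @describeIn SizeFactors normalization scheme accessor.
#' @export
sfMethod <- function(x) x@method

setMethod("show", "SizeFactors", function(object) {
    cat("SizeFactors (", object@method, "), ", length(object@s),
        " samples\n", sep = "")
    print(head(round(object@s, 4), 6))
})

#' Per-taxon zero-inflated negative binomial fits
#'
#' One ZINB mixture per taxon: counts arise from NB(mu, phi) with
#' probability 1 - pi and from a point mass at zero (structural zero) with
#' probability pi; log mu is the regression on the design plus the log
#' size-factor offset, logit pi a regression on the zero-model design.
#'
#' @slot betaMu taxa x p coefficient matrix of the log-mean model.
#' @slot betaPi taxa x q coefficient matrix of the logit zero-inflation
#'   model.
#' @slot phi per-taxon NB dispersion.
#' @slot mu,pi taxa x samples fitted means / structural-zero probabilities.
#' @slot loglik per-taxon observed-data log-likelihood at the optimum.
#' @slot converged,nIter per-taxon EM status.
#' @aliases ZinbFit-class
#' @exportClass ZinbFit
setClass("ZinbFit",
         representation(betaMu = "matrix", betaPi = "matrix",
                        phi = "numeric", mu = "matrix", pi = "matrix",
                        loglik = "numeric", converged = "logical",
                        nIter = "integer"))

setValidity("ZinbFit", function(object) {
    msg <- NULL
    if (any(!is.finite(object@phi)) || any(object@phi < 0))
        msg <- c(msg, "phi must be finite and non-negative")
    if (any(object@pi <= 0) || any(object@pi >= 1))
        msg <- c(msg, "fitted pi must lie in (0,1)")
    if (any(object@mu <= 0))
        msg <- c(msg, "fitted mu must be positive")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "ZinbFit", function(object) {
    cat("ZinbFit:", nrow(object@mu), "taxa,", ncol(object@mu), "samples\n")
    cat(sprintf("converged: %d/%d; median phi: %.3g; median mean pi: %.3g\n",
                sum(object@converged), length(object@converged),
                median(object@phi), median(rowMeans(object@pi))))
})

#' Zero-inflated log-normal simulation template
#'
#' Per-taxon parameters of the generator: prevalence (probability a taxon
#' is present in a sample), mean and sd of the log non-zero relative
#' abundance, plus a global library-size model (log-normal around a median
#' depth).
#'
#' @slot taxonIds taxon identifiers.
#' @slot prevalence per-taxon presence probability in [0,1].
#' @slot m per-taxon mean of log non-zero relative abundance.
#' @slot sd per-taxon sd of log non-zero relative abundance (floored).
#' @slot depthLocation median library size (> 0).
#' @slot depthLogSd sd of log library size.
#' @aliases SimTemplate-class
#' @exportClass SimTemplate
setClass("SimTemplate",
         representation(taxonIds = "character", prevalence = "numeric",
                        m = "numeric", sd = "numeric",
                        depthLocation = "numeric", depthLogSd = "numeric"))

setValidity("SimTemplate", function(object) {
    msg <- NULL
    J <- length(object@taxonIds)
    if (length(object@prevalence) != J || length(object@m) != J ||
        length(object@sd) != J)
        msg <- c(msg, "per-taxon slots must have equal length")
    if (any(object@prevalence < 0 | object@prevalence > 1))
        msg <- c(msg, "prevalence must lie in [0,1]")
    if (any(object@sd < 0))
        msg <- c(msg, "sd must be non-negative")
    if (object@depthLocation <= 0)
        msg <- c(msg, "depthLocation must be positive")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "SimTemplate", function(object) {
    cat("SimTemplate:", length(object@taxonIds), "taxa; median depth",
        format(object@depthLocation, big.mark = ","),
        sprintf("(log sd %.2f)\n", object@depthLogSd))
    cat(sprintf("mean prevalence %.3f\n", mean(object@prevalence)))
})

#' Ground-truth spike-in design for benchmarking
#'
#' @slot taxonIds identifiers of the spiked taxa.
#' @slot delta named natural-log fold change per spiked taxon (non-zero;
#'   sign encodes direction).
#' @aliases SpikeDesign-class
#' @exportClass SpikeDesign
setClass("SpikeDesign",
         representation(taxonIds = "character", delta = "numeric"))

setValidity("SpikeDesign", function(object) {
    msg <- NULL
    if (length(object@taxonIds) != length(object@delta))
        msg <- c(msg, "taxonIds and delta must have equal length")
    if (any(object@delta == 0))
        msg <- c(msg, "spiked taxa must have non-zero delta")
    if (anyDuplicated(object@taxonIds))
        msg <- c(msg, "duplicated spiked taxon ids")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "SpikeDesign", function(object) {
    cat("SpikeDesign:", length(object@taxonIds), "spiked taxa; |delta| =",
        paste(unique(abs(object@delta)), collapse = ", "), "\n")
})

#' Differential abundance result table
#'
#' A \linkS4class{DataFrame} subclass with one row per tested taxon and
#' the fixed columns \code{taxon_id}, \code{base_mean}, \code{log2fc},
#' \code{stat}, \code{df}, \code{pvalue}, \code{padj},
#' \code{structured_zero}, \code{path}.
#'
#' @aliases DAResults-class
#' @exportClass DAResults
setClass("DAResults", contains = "DFrame")

.daCols <- c("taxon_id", "base_mean", "log2fc", "stat", "df",
             "pvalue", "padj", "structured_zero", "path")

setValidity("DAResults", function(object) {
    msg <- NULL
    if (!all(.daCols %in% colnames(object)))
        msg <- c(msg, paste("missing columns:",
                            paste(setdiff(.daCols, colnames(object)),
                                  collapse = ", ")))
    else {
        ok <- !is.na(object$stat)
        if (any(object$stat[ok] < 0))
            msg <- c(msg, "stat must be >= 0")
        for (cn in c("pvalue", "padj")) {
            v <- object[[cn]]
            if (any(v < 0 | v > 1, na.rm = TRUE))
                msg <- c(msg, paste(cn, "must lie in [0,1]"))
        }
        if (!all(object$path %in% c("partA", "partB")))
            msg <- c(msg, "path must be 'partA' or 'partB'")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a DAResults table
#'
#' @param df a \code{data.frame} or \code{DataFrame} with the required
#'   columns.
#' @return a \linkS4class{DAResults}.
#' @export
DAResults <- function(df) {
    df <- DataFrame(df)
    missing <- setdiff(.daCols, colnames(df))
    if (length(missing))
        stop("missing result columns: ", paste(missing, collapse = ", "))
    new("DAResults", df[, union(.daCols, colnames(df))])
}

setMethod("show", "DAResults", function(object) {
    cat("DAResults:", nrow(object), "taxa;",
        sum(object$padj < metadata(object)$alpha %||% 0.05, na.rm = TRUE),
        "significant\n")
    callNextMethod()
})

`%||%` <- function(a, b) if (is.null(a)) b else a
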