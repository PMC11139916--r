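## End-to-end orchestration of the two-path differential abundance
## strategy, design construction and diagnostic summaries.

#' Build nested full/reduced design matrices
#'
#' Treatment coding versus a reference level: the full design is the
#' intercept plus one dummy per non-reference level; the reduced design
#' drops the dummy of the tested level (for a two-level factor this
#' leaves the intercept alone). For a three-level factor {N, P, C} with
#' reference C and test level N, the full columns are {1, N, P} and the
#' reduced {1, P}.
#'
#' @param meta sample metadata \code{data.frame}.
#' @param factor name of the metadata column to test.
#' @param reference reference level (must be observed).
#' @param testLevel level whose effect is tested; defaults to the single
#'   non-reference level of a two-level factor (required otherwise).
#' @return list with \code{full}, \code{reduced} (matrices with sample
#'   row names), \code{testCoef} (name of the tested column),
#'   \code{groups} (the releveled factor).
#' @export
buildDesign <- function(meta, factor, reference, testLevel = NULL) {
    if (!factor %in% colnames(meta))
        stop("factor '", factor, "' not found in metadata")
    f <- droplevels(as.factor(meta[[factor]]))
    if (any(is.na(f)))
        stop("missing level for samples: ",
             paste(rownames(meta)[is.na(f)], collapse = ", "))
    if (nlevels(f) < 2L)
        stop("factor '", factor, "' needs at least two observed levels")
    if (!reference %in% levels(f))
        stop("reference level '", reference, "' not observed in '",
             factor, "'")
    f <- stats::relevel(f, ref = reference)
    if (is.null(testLevel)) {
        if (nlevels(f) != 2L)
            stop("testLevel must be given for factors with more than ",
                 "two levels")
        testLevel <- setdiff(levels(f), reference)
    }
    if (!testLevel %in% levels(f) || testLevel == reference)
        stop("testLevel '", testLevel, "' is not a non-reference level")
    full <- model.matrix(~f)
    colnames(full) <- c("(Intercept)", paste0(factor, levels(f)[-1]))
    rownames(full) <- rownames(meta)
    testCoef <- paste0(factor, testLevel)
    reduced <- full[, setdiff(colnames(full), testCoef), drop = FALSE]
    list(full = full, reduced = reduced, testCoef = testCoef,
         groups = f)
}

#' Run the combined two-path differential abundance analysis
#'
#' Two-group mode: filter low-abundance taxa, classify group-wise
#' structured zeros, compute size factors once on the filtered table,
#' then test structured taxa with the unweighted ridge NB LRT (part A)
#' and the remaining taxa with the ZINB-weighted ridge NB LRT (part B);
#' BH adjustment is per part by default. Multi-covariate mode (used for
#' factors with more than two levels, where the structured-zero notion
#' is contrast-specific): classification is skipped for testing; every
#' filtered taxon is analyzed both unweighted (part A rows) and weighted
#' (part B rows), each analysis BH-adjusted separately, and the stacked
#' table lets the caller collect the union of significant taxa; the
#' structured-zero flag is still reported for the tested contrast
#' (computed on the reference- and test-level samples only).
#'
#' @param counts taxa x samples count matrix (or
#'   \linkS4class{MicrobExperiment}, whose colData supplies \code{meta}).
#' @param meta sample metadata \code{data.frame} (ignored when
#'   \code{counts} is a \code{MicrobExperiment}).
#' @param factor,reference,testLevel see [buildDesign()].
#' @param mode \code{"two_group"} or \code{"multi_covariate"}.
#' @param normalization size-factor scheme (default poscounts).
#' @param minCount,minSamples,scope filter settings, see
#'   [filterLowAbundance()].
#' @param weighting apply ZINB observation weights in part B
#'   (default TRUE; FALSE makes both paths unweighted).
#' @param weightModel weight model passed to [zinbWeights()]
#'   (default \code{"pooled"}).
#' @param ridge ridge penalty (default 1e-6).
#' @param alpha significance level recorded in the result metadata.
#' @param bhScope \code{"per_part"} (default) or \code{"joint"} BH
#'   adjustment.
#' @param piIntercept logical; restrict the zero-inflation model to an
#'   intercept (useful for very small groups).
#' @param declareStructuredSignificant logical; if TRUE, structured-zero
#'   taxa are declared significant without testing (padj 0, pvalue NA).
#' @return a \linkS4class{DAResults}; metadata records the stage taxon
#'   counts, alpha, mode and options.
#' @export
runCombined <- function(counts, meta = NULL, factor, reference,
                        testLevel = NULL,
                        mode = c("two_group", "multi_covariate"),
                        normalization = c("poscounts", "tmm", "gmpr"),
                        minCount = 2L, minSamples = 2L,
                        scope = "any_group", weighting = TRUE,
                        weightModel = c("pooled", "per_taxon"),
                        ridge = 1e-6, alpha = 0.05,
                        bhScope = c("per_part", "joint"),
                        piIntercept = FALSE,
                        declareStructuredSignificant = FALSE) {
    mode <- match.arg(mode)
    normalization <- match.arg(normalization)
    bhScope <- match.arg(bhScope)
    weightModel <- match.arg(weightModel)
    stopifnot(alpha > 0, alpha < 1)
    if (is(counts, "MicrobExperiment")) {
        meta <- as.data.frame(colData(counts))
        counts <- counts(counts)
    }
    al <- alignTables(counts, meta)
    counts <- al$counts; meta <- al$meta
    des <- withStage("design", buildDesign(meta, factor, reference,
                                           testLevel))
    groups <- des$groups
    flt <- withStage("filter",
                     filterLowAbundance(counts, groups, minCount,
                                        minSamples, scope))
    fc <- flt$counts
    if (nrow(fc) == 0L)
        stop("pipeline stage 'filter': no taxa passed the filter")
    sf <- withStage("normalize", computeSizeFactors(fc, normalization))
    Xpi <- if (piIntercept)
        matrix(1, ncol(fc), 1, dimnames = list(colnames(fc),
                                               "(Intercept)"))
    else NULL

    testPart <- function(subCounts, useWeights) {
        if (nrow(subCounts) == 0L)
            return(data.frame(taxon_id = character(0),
                              base_mean = numeric(0), log2fc = numeric(0),
                              stat = numeric(0), df = integer(0),
                              pvalue = numeric(0)))
        w <- NULL
        if (useWeights)
            w <- withStage("zinb",
                           zinbWeights(subCounts, des$full, sf,
                                       model = weightModel, Xpi = Xpi,
                                       ridge = ridge))
        withStage("test", nbTestTaxa(subCounts, des$full, des$reduced,
                                     sf, weights = w, ridge = ridge))
    }

    if (mode == "two_group") {
        part <- withStage("classify", classifyStructuredZeros(fc, groups))
        strA <- fc[part$structured, , drop = FALSE]
        strB <- fc[part$nonstructured, , drop = FALSE]
        if (declareStructuredSignificant) {
            resA <- data.frame(
                taxon_id = rownames(strA),
                base_mean = if (nrow(strA))
                    rowMeans(sweep(strA, 2, sfValues(sf), "/"))
                else numeric(0),
                log2fc = NA_real_, stat = NA_real_, df = NA_integer_,
                pvalue = NA_real_, stringsAsFactors = FALSE)
        } else resA <- testPart(strA, useWeights = FALSE)
        resB <- testPart(strB, useWeights = weighting)
        resA$structured_zero <- rep(TRUE, nrow(resA))
        resB$structured_zero <- rep(FALSE, nrow(resB))
        resA$path <- rep("partA", nrow(resA))
        resB$path <- rep("partB", nrow(resB))
        res <- rbind(resA, resB)
        if (bhScope == "per_part") {
            res$padj <- NA_real_
            for (pp in c("partA", "partB")) {
                sel <- res$path == pp
                res$padj[sel] <- adjustBH(res$pvalue[sel])
            }
        } else res$padj <- adjustBH(res$pvalue)
        if (declareStructuredSignificant)
            res$padj[res$path == "partA"] <- 0
        res <- res[match(rownames(fc), res$taxon_id), ]
        stages <- list(input = nrow(counts), filtered = nrow(fc),
                       partA = nrow(strA), partB = nrow(strB))
    } else {
        # structured-zero flag for the tested contrast only
        lvl <- sub(paste0("^", factor), "", des$testCoef)
        inContrast <- groups %in% c(reference, lvl)
        flag <- tryCatch({
            p <- classifyStructuredZeros(fc[, inContrast, drop = FALSE],
                                         droplevels(groups[inContrast]))
            rownames(fc) %in% p$structured
        }, error = function(e) rep(NA, nrow(fc)))
        resA <- testPart(fc, useWeights = FALSE)
        resB <- testPart(fc, useWeights = weighting)
        resA$structured_zero <- resB$structured_zero <- flag
        resA$path <- rep("partA", nrow(resA))
        resB$path <- rep("partB", nrow(resB))
        resA$padj <- adjustBH(resA$pvalue)
        resB$padj <- adjustBH(resB$pvalue)
        res <- rbind(resA, resB)
        if (bhScope == "joint")
            res$padj <- adjustBH(res$pvalue)
        stages <- list(input = nrow(counts), filtered = nrow(fc),
                       structured_contrast = sum(flag, na.rm = TRUE))
    }
    out <- DAResults(res)
    metadata(out) <- list(alpha = alpha, mode = mode,
                          normalization = normalization,
                          bhScope = bhScope, weighting = weighting,
                          ridge = ridge, stages = stages,
                          testCoef = des$testCoef)
    out
}

#' Significant taxa of a result table
#'
#' In multi-covariate mode a taxon is significant when either analysis
#' path calls it (the union rule).
#'
#' @param res a \linkS4class{DAResults}.
#' @param alpha threshold on \code{padj}; default the alpha recorded in
#'   the result metadata.
#' @return character vector of significant taxon ids.
#' @export
significantTaxa <- function(res, alpha = NULL) {
    if (is.null(alpha)) alpha <- metadata(res)$alpha %||% 0.05
    unique(res$taxon_id[!is.na(res$padj) & res$padj < alpha])
}

#' @keywords internal
#' @noRd
withStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", stage, "': ", conditionMessage(e),
             call. = FALSE))
}

#' Biological coefficient of variation data
#'
#' BCV_j = sqrt(phi_j), paired with the taxon's average log2 CPM, the
#' plot data used to visualize how zero inflation drives dispersion
#' (high-zero taxa form high-BCV stripes).
#'
#' @param counts taxa x samples count matrix.
#' @param X design matrix.
#' @param sizeFactors \linkS4class{SizeFactors} or positive vector.
#' @param ... passed to [estimateDispersion()].
#' @return \code{data.frame} with \code{taxon_id}, \code{aveLogCPM},
#'   \code{bcv}.
#' @export
bcvData <- function(counts, X, sizeFactors, ...) {
    phi <- estimateDispersion(counts, X, sizeFactors, ...)
    data.frame(taxon_id = rownames(counts),
               aveLogCPM = rowMeans(logCPM(counts)),
               bcv = sqrt(phi), row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Relative-abundance matrix for heatmaps of significant taxa
#'
#' Per-sample relative abundances (count / library size) restricted to a
#' taxon subset; columns ordered by group, rows by decreasing effect
#' size when given. Deterministic ordering (ties broken by id) so
#' repeated calls agree.
#'
#' @param counts taxa x samples count matrix.
#' @param taxa non-empty character vector of taxa to display.
#' @param groups optional per-sample group labels for column ordering.
#' @param log2fc optional named effect sizes for row ordering.
#' @return relative-abundance matrix with entries in [0, 1].
#' @export
heatmapData <- function(counts, taxa, groups = NULL, log2fc = NULL) {
    if (length(taxa) == 0L) stop("empty taxon subset")
    lib <- colSums(counts)
    rel <- sweep(counts[taxa, , drop = FALSE], 2, pmax(lib, 1), "/")
    if (!is.null(groups)) {
        ord <- order(as.factor(groups), colnames(rel))
        rel <- rel[, ord, drop = FALSE]
    }
    if (!is.null(log2fc)) {
        e <- log2fc[taxa]
        rel <- rel[order(-e, taxa), , drop = FALSE]
    }
    rel
}
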