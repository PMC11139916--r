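## Low-abundance filtering, structured-zero classification, sparsity
## summaries.

.asGroups <- function(groups, n) {
    groups <- as.factor(groups)
    if (length(groups) != n)
        stop("group labels must cover all samples")
    if (any(is.na(groups)))
        stop("missing group label")
    droplevels(groups)
}

#' Filter low-abundance taxa
#'
#' A taxon is kept iff, within at least one treatment group (the default
#' \code{scope = "any_group"}), at least \code{minSamples} samples have a
#' count of at least \code{minCount}. \code{scope = "all_groups"} requires
#' the condition in every group and \code{scope = "all_samples"} ignores
#' the grouping. The default thresholds (2 counts in 2 samples) retain
#' rare but replicated taxa.
#'
#' @param counts taxa x samples count matrix.
#' @param groups per-sample group labels (factor-like).
#' @param minCount minimum count per qualifying sample (>= 1).
#' @param minSamples minimum number of qualifying samples (>= 1).
#' @param scope where the condition must hold; see Details.
#' @return list with \code{counts} (kept rows, original order) and
#'   \code{kept} (logical mask over the original taxa).
#' @examples
#' m <- rbind(a = c(0L, 3L, 3L, 0L, 0L, 0L), b = c(1L, 1L, 1L, 1L, 1L, 1L))
#' colnames(m) <- paste0("s", 1:6)
#' filterLowAbundance(m, rep(c("x", "y"), each = 3))$kept  # a TRUE, b FALSE
#' @export
filterLowAbundance <- function(counts, groups, minCount = 2L,
                               minSamples = 2L,
                               scope = c("any_group", "all_groups",
                                         "all_samples")) {
    scope <- match.arg(scope)
    stopifnot(minCount >= 1L, minSamples >= 1L)
    groups <- .asGroups(groups, ncol(counts))
    if (nlevels(groups) < 1L) stop("at least one group required")
    hits <- vapply(levels(groups), function(g) {
        rowSums(counts[, groups == g, drop = FALSE] >= minCount) >= minSamples
    }, logical(nrow(counts)))
    hits <- matrix(hits, nrow = nrow(counts))
    kept <- switch(scope,
                   any_group = rowSums(hits) >= 1L,
                   all_groups = rowSums(hits) == nlevels(groups),
                   all_samples =
                       rowSums(counts >= minCount) >= minSamples)
    if (!any(kept))
        warning("no taxa pass the abundance filter")
    list(counts = counts[kept, , drop = FALSE],
         kept = setNames(kept, rownames(counts)))
}

#' Classify taxa by group-wise structured zeros
#'
#' For a two-group comparison, a taxon has group-wise structured zeros
#' when its counts are zero in every sample of one group while it has at
#' least one positive count overall. Such taxa cause perfect separation
#' in unpenalized count regression. Classification uses observed zeros
#' only.
#'
#' @param counts filtered taxa x samples count matrix.
#' @param groups per-sample labels with exactly two observed groups.
#' @return list with character vectors \code{structured} and
#'   \code{nonstructured} partitioning the row names.
#' @examples
#' m <- rbind(a = c(0L, 0L, 0L, 2L, 5L, 9L), b = c(0L, 4L, 0L, 1L, 0L, 2L))
#' colnames(m) <- paste0("s", 1:6)
#' classifyStructuredZeros(m, rep(c("x", "y"), each = 3))
#' @export
classifyStructuredZeros <- function(counts, groups) {
    groups <- .asGroups(groups, ncol(counts))
    if (nlevels(groups) != 2L)
        stop("structured-zero classification is defined for exactly two ",
             "groups; for multi-level factors use the multi-covariate ",
             "pipeline path (runCombined(mode = 'multi_covariate'))")
    g1 <- groups == levels(groups)[1]
    zero1 <- rowSums(counts[, g1, drop = FALSE]) == 0L
    zero2 <- rowSums(counts[, !g1, drop = FALSE]) == 0L
    anyPos <- rowSums(counts) > 0L
    structured <- (zero1 | zero2) & anyPos
    list(structured = rownames(counts)[structured],
         nonstructured = rownames(counts)[!structured & anyPos])
}

#' Fraction of zero cells in a count matrix
#'
#' @param counts non-empty count matrix.
#' @return fraction of entries equal to zero, in [0,1].
#' @export
zeroFraction <- function(counts) {
    if (length(counts) == 0L) stop("empty count matrix")
    mean(counts == 0)
}
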