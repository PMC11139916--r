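## Scoring calls against truth and aggregating type I error, FDR and
## power over replicated simulations.

#' Confusion counts between truth and calls
#'
#' TP: spiked and called; FP: not spiked but called; TN: not spiked and
#' not called; FN: spiked but not called.
#'
#' @param truth logical vector of ground-truth spiked flags.
#' @param calls logical vector of significance calls, aligned to
#'   \code{truth}.
#' @return named integer vector \code{c(TP, FP, TN, FN)}.
#' @export
confusionCounts <- function(truth, calls) {
    if (length(truth) != length(calls))
        stop("truth and calls must have equal length")
    truth <- as.logical(truth); calls <- as.logical(calls)
    c(TP = sum(truth & calls), FP = sum(!truth & calls),
      TN = sum(!truth & !calls), FN = sum(truth & !calls))
}

#' Power and FDR from confusion counts
#'
#' power = TP / (TP + FN), NaN when no taxa are spiked; fdr = FP /
#' (TP + FP), defined as 0 when there are no discoveries (so replicates
#' without discoveries can be averaged).
#'
#' @param conf output of [confusionCounts()].
#' @return list with \code{power} and \code{fdr}.
#' @export
daMetrics <- function(conf) {
    pos <- conf[["TP"]] + conf[["FN"]]
    disc <- conf[["TP"]] + conf[["FP"]]
    list(power = if (pos == 0) NaN else conf[["TP"]] / pos,
         fdr = if (disc == 0) 0 else conf[["FP"]] / disc)
}

#' Observed type I error rate
#'
#' Fraction of null p-values below \code{alpha}; missing p-values are
#' excluded from both numerator and denominator.
#'
#' @param pvalues p-values of null (non-spiked) taxa.
#' @param alpha nominal level (default 0.05).
#' @return rate in [0,1]; NaN for an empty vector.
#' @export
typeOneError <- function(pvalues, alpha = 0.05) {
    p <- pvalues[!is.na(pvalues)]
    if (any(p < 0 | p > 1)) stop("p-values must lie in [0,1]")
    if (length(p) == 0L) return(NaN)
    mean(p < alpha)
}

#' Single-replicate simulation analysis
#'
#' Simulates one dataset, filters, classifies and (by default) excludes
#' structured-zero taxa, normalizes, runs the NB LRT (weighted or not)
#' and BH-adjusts; returns per-replicate scores.
#' @keywords internal
#' @noRd
.benchmarkRep <- function(template, nPerGroup, effect, seed, method,
                          alpha, spikeFrac, excludeStructured,
                          normalization, ridge, piIntercept,
                          weightModel = "pooled") {
    spike <- if (effect > 0)
        makeSpikeDesign(template, effect, spikeFrac, seed) else NULL
    ds <- simulateDataset(template, nPerGroup, spike, seed)
    m <- counts(ds)
    groups <- colData(ds)$group
    flt <- suppressWarnings(filterLowAbundance(m, groups))
    fc <- flt$counts
    if (nrow(fc) < 2L) stop("too few taxa after filtering")
    part <- classifyStructuredZeros(fc, groups)
    tested <- if (excludeStructured) part$nonstructured
              else c(part$structured, part$nonstructured)
    fc <- fc[rownames(fc) %in% tested, , drop = FALSE]
    if (nrow(fc) < 2L) stop("too few taxa after structured-zero exclusion")
    sf <- computeSizeFactors(fc, normalization)
    meta <- data.frame(group = groups, row.names = colnames(fc))
    des <- buildDesign(meta, "group", "control")
    w <- NULL
    if (method == "weighted") {
        Xpi <- if (piIntercept)
            matrix(1, ncol(fc), 1,
                   dimnames = list(colnames(fc), "(Intercept)"))
        else NULL
        w <- zinbWeights(fc, des$full, sf, model = weightModel,
                         Xpi = Xpi, ridge = ridge)
    }
    res <- nbTestTaxa(fc, des$full, des$reduced, sf, weights = w,
                      ridge = ridge)
    res$padj <- adjustBH(res$pvalue)
    truth <- rowData(ds)[res$taxon_id, "spiked"]
    calls <- !is.na(res$padj) & res$padj < alpha
    conf <- confusionCounts(truth, calls)
    met <- daMetrics(conf)
    data.frame(power = met$power, fdr = met$fdr,
               t1e = typeOneError(res$pvalue[!truth], alpha),
               n_tested = nrow(res), n_sig = sum(calls))
}

#' Run a simulation benchmark grid
#'
#' For every (method, samples-per-group, effect) cell, simulates
#' \code{nReps} datasets (replicate seeds are \code{baseSeed +
#' replicate index}, shared across cells so comparisons are paired),
#' applies the standard protocol — filter, classify and exclude
#' structured-zero taxa, normalize, test, BH-adjust — and scores each
#' replicate. Null cells (effect 0) report the observed type I error;
#' spiked cells report power and FDR. A replicate on which a method
#' fails is recorded with NA scores and the failure message; aggregates
#' should be taken over the successes.
#'
#' @param template a \linkS4class{SimTemplate}.
#' @param methods character subset of \code{c("weighted",
#'   "unweighted")}.
#' @param nPerGroup integer vector of per-group sample sizes.
#' @param effects numeric vector of absolute log-fold effects (0 =
#'   null).
#' @param nReps replicates per cell (default 20).
#' @param baseSeed base seed; replicate r uses \code{baseSeed + r}.
#' @param alpha significance level for calls (on BH-adjusted p-values)
#'   and for the type I error rate (on raw p-values).
#' @param spikeFrac fraction of taxa spiked (default 0.1).
#' @param excludeStructured drop structured-zero taxa before testing
#'   (default TRUE, the simulation protocol).
#' @param normalization size-factor scheme.
#' @param ridge ridge penalty.
#' @param piIntercept restrict the ZINB zero model to an intercept
#'   (only relevant for \code{weightModel = "per_taxon"}).
#' @param weightModel weight model passed to [zinbWeights()].
#' @return long \code{data.frame}: method, n_per_group, effect, rep,
#'   seed, power, fdr, t1e, n_tested, n_sig, error.
#' @export
runBenchmark <- function(template, methods = c("weighted", "unweighted"),
                         nPerGroup = c(5, 25), effects = c(0, 1, 2),
                         nReps = 20L, baseSeed = 1L, alpha = 0.05,
                         spikeFrac = 0.1, excludeStructured = TRUE,
                         normalization = "poscounts", ridge = 1e-6,
                         piIntercept = FALSE,
                         weightModel = c("pooled", "per_taxon")) {
    methods <- match.arg(methods, c("weighted", "unweighted"),
                         several.ok = TRUE)
    weightModel <- match.arg(weightModel)
    rows <- list()
    for (method in methods)
        for (n in nPerGroup)
            for (eff in effects)
                for (r in seq_len(nReps)) {
                    seed <- baseSeed + r
                    rec <- tryCatch({
                        out <- .benchmarkRep(template, n, eff, seed,
                                             method, alpha, spikeFrac,
                                             excludeStructured,
                                             normalization, ridge,
                                             piIntercept, weightModel)
                        out$error <- FALSE
                        out
                    }, error = function(e)
                        data.frame(power = NA_real_, fdr = NA_real_,
                                   t1e = NA_real_,
                                   n_tested = NA_integer_,
                                   n_sig = NA_integer_, error = TRUE))
                    rows[[length(rows) + 1L]] <-
                        cbind(data.frame(method = method,
                                         n_per_group = n, effect = eff,
                                         rep = r, seed = seed),
                              rec)
                }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Aggregate benchmark cell means
#'
#' @param bench output of [runBenchmark()].
#' @return \code{data.frame} of per-cell means (over non-failed
#'   replicates) of power, fdr and type I error, with replicate counts.
#' @export
benchmarkSummary <- function(bench) {
    ok <- bench[!bench$error, , drop = FALSE]
    agg <- aggregate(ok[, c("power", "fdr", "t1e")],
                     by = ok[, c("method", "n_per_group", "effect")],
                     FUN = function(x) mean(x, na.rm = TRUE))
    nrep <- aggregate(list(n_ok = ok$rep),
                      by = ok[, c("method", "n_per_group", "effect")],
                      FUN = length)
    merge(agg, nrep)
}
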