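#' @importFrom limma voom lmFit squeezeVar
#' @importFrom edgeR filterByExpr calcNormFactors
#' @importFrom stats model.matrix setNames ave pt p.adjust rnbinom runif
#'   rlnorm ks.test
NULL

# Two-group design from the condition labels; contrast = second level.
designFromConditions <- function(object) {
    cond <- conditions(object)
    if (is.null(cond))
        stop("no condition labels; supply a design matrix explicitly")
    cond <- factor(cond)
    if (nlevels(cond) < 2) stop("need at least two condition levels")
    stats::model.matrix(~cond)
}

#' Filter bins by expression level
#'
#' Keeps bins with enough reads to support inference: at least
#' \code{min.count} reads (on the CPM scale of the median library size) in at
#' least as many samples as the smallest experimental group, and at least
#' \code{min.total.count} reads in total (the conventional
#' \code{filterByExpr} rule).
#'
#' @param object a \code{BinnedCounts}.
#' @param design design matrix; defaults to a two-group design built from the
#'   condition labels.
#' @param min.count,min.total.count filtering thresholds.
#' @return The filtered \code{BinnedCounts}; the retained index set is stored
#'   in \code{metadata(x)$filter}.
#' @export
filterBins <- function(object, design = NULL, min.count = 10,
                       min.total.count = 15) {
    if (is.null(design)) design <- designFromConditions(object)
    keep <- edgeR::filterByExpr(binCounts(object), design = design,
                                lib.size = libSizes(object),
                                min.count = min.count,
                                min.total.count = min.total.count)
    if (!any(keep))
        stop("no bin passes the expression filter; review min.count/",
             "min.total.count relative to sequencing depth")
    out <- object[keep, ]
    metadata(out)$filter <- list(min.count = min.count,
                                 min.total.count = min.total.count,
                                 kept = which(keep), total = length(keep))
    out
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Computes TMM factors (reference library chosen by the 75th-percentile CPM
#' rule; 30\% trimming on M-values, 5\% on A-values; precision weighting)
#' and stores them in \code{normFactors()}. Factors multiply to 1 across
#' samples. An all-zero sample keeps factor 1 with a warning.
#'
#' @param object a \code{BinnedCounts}.
#' @return The object with normalization factors filled.
#' @export
tmmNormFactors <- function(object) {
    cnt <- binCounts(object)
    empty <- colSums(cnt) == 0
    nf <- rep(1, ncol(cnt))
    if (any(empty))
        warning("sample(s) with all-zero counts get normalization factor 1: ",
                paste(colnames(object)[empty], collapse = ", "))
    if (any(!empty))
        nf[!empty] <- edgeR::calcNormFactors(cnt[, !empty, drop = FALSE],
                                             lib.size = libSizes(object)[!empty],
                                             method = "TMM")
    normFactors(object) <- nf
    object
}

#' Precision weights from the mean-variance trend
#'
#' log2-CPM values are computed with a 0.5-count offset against effective
#' library sizes (library size x TMM factor, + 1); the square-root residual
#' standard deviations are regressed on average log2 counts by lowess
#' (span 0.5) and observation weights are the inverse squared trend at each
#' fitted log-count (the voom procedure). Extrapolation beyond the fitted
#' range is clamped to the boundary value.
#'
#' @param object a filtered, normalized \code{BinnedCounts}.
#' @param design design matrix (default: two-group from conditions).
#' @return An \code{EList} with log-expression \code{E} and \code{weights}.
#' @export
voomWeights <- function(object, design = NULL) {
    if (is.null(design)) design <- designFromConditions(object)
    if (nrow(design) - qr(design)$rank < 1)
        stop("fewer than 1 residual degree of freedom")
    limma::voom(binCounts(object), design = design,
                lib.size = libSizes(object) * normFactors(object))
}

#' Weighted least-squares fit per bin
#'
#' Fits the linear model gene-bin-wise by weighted least squares with the
#' precision weights, recording the coefficients, the unscaled standard
#' deviations (square roots of the diagonal of \eqn{(X^T V X)^{-1}}), the
#' residual variances and the residual degrees of freedom.
#'
#' @param elist \code{EList} from \code{\link{voomWeights}}.
#' @param design design matrix (full column rank required).
#' @return An \code{MArrayLM} fit.
#' @export
fitBinModels <- function(elist, design) {
    if (qr(design)$rank < ncol(design))
        stop("design matrix is rank-deficient")
    limma::lmFit(elist, design)
}

#' Empirical-Bayes squeezing of residual variances
#'
#' Moment-matches a scaled F distribution to the residual variances to
#' estimate a prior (d0, s0^2) and returns posterior variances
#' \eqn{s^2 = (d0 s0^2 + d \hat\sigma^2) / (d0 + d)}. With
#' \code{perBin = TRUE} (the improved statistic) bin-level variances are
#' squeezed directly; with \code{perBin = FALSE} (the classical statistic)
#' variances are first averaged within genes and the gene-level values are
#' squeezed. Identical input variances give an infinite prior df and
#' posteriors equal to the common value.
#'
#' @param s2 residual variances.
#' @param df residual degrees of freedom (scalar or per-entry).
#' @param perBin squeeze bin-level values (\code{TRUE}) or gene-averaged
#'   values (\code{FALSE}).
#' @param gene gene ids (required when \code{perBin = FALSE}).
#' @param robust use limma's robust prior estimation (default \code{FALSE}).
#' @return A list with \code{df.prior}, \code{var.prior}, \code{var.post}
#'   (per bin or per gene), \code{df} (the df paired with \code{var.post})
#'   and \code{level} (\code{"bin"} or \code{"gene"}).
#' @export
squeezeVariances <- function(s2, df, perBin = TRUE, gene = NULL,
                             robust = FALSE) {
    df <- rep_len(df, length(s2))
    if (perBin) {
        sq <- limma::squeezeVar(s2, df, robust = robust)
        list(df.prior = sq$df.prior, var.prior = sq$var.prior,
             var.post = sq$var.post, df = df, level = "bin")
    } else {
        if (is.null(gene)) stop("gene ids required for gene-level squeezing")
        gene <- as.character(gene)
        n <- rowsum(rep(1, length(s2)), gene, reorder = FALSE)[, 1]
        gene.s2 <- rowsum(s2, gene, reorder = FALSE)[, 1] / n
        gene.df <- rowsum(df, gene, reorder = FALSE)[, 1]
        sq <- limma::squeezeVar(gene.s2, gene.df, robust = robust)
        list(df.prior = sq$df.prior, var.prior = sq$var.prior,
             var.post = setNames(sq$var.post, names(n)),
             df = setNames(gene.df, names(n)), level = "gene")
    }
}

#' Full pre-processing and per-bin model fit
#'
#' Runs the chain filter -> TMM -> voom -> weighted least squares and returns
#' the per-bin fit together with the objects needed by
#' \code{\link{diffSpliceBins}}.
#'
#' @param object a \code{BinnedCounts}.
#' @param design design matrix (default: two-group from conditions).
#' @param coef column of the design matrix to test (default: last).
#' @return A list of class \code{BinFit}: \code{fit} (MArrayLM),
#'   \code{elist}, \code{design}, \code{coef}, \code{counts} (the filtered
#'   \code{BinnedCounts}).
#' @export
fitBins <- function(object, design = NULL, coef = NULL) {
    if (is.null(design)) design <- designFromConditions(object)
    if (is.null(coef)) coef <- ncol(design)
    fc <- filterBins(object, design)
    fc <- tmmNormFactors(fc)
    v <- voomWeights(fc, design)
    fit <- fitBinModels(v, design)
    structure(list(fit = fit, elist = v, design = design, coef = coef,
                   counts = fc),
              class = "BinFit")
}

#' @export
print.BinFit <- function(x, ...) {
    cat(sprintf("BinFit: %d bins, %d samples, %d coefficients (testing '%s')\n",
                nrow(x$fit), nrow(x$design), ncol(x$design),
                colnames(x$design)[x$coef]))
    invisible(x)
}

#' Export the per-bin fit for audit
#'
#' @param binfit a \code{BinFit}.
#' @param path TSV output path.
#' @export
writeFitTable <- function(binfit, path) {
    fit <- binfit$fit
    df <- data.frame(bin = rownames(binfit$counts),
                     gene = geneIds(binfit$counts),
                     beta = fit$coefficients[, binfit$coef],
                     u = fit$stdev.unscaled[, binfit$coef],
                     sigma2 = fit$sigma^2, df.residual = fit$df.residual,
                     aveLogExpr = rowMeans(binfit$elist$E))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# binsplice fit v1", con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
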