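#' Bin-vs-gene moderated t-statistics
#'
#' The workhorse behind \code{\link{diffSpliceBins}}, operating on plain
#' vectors so it can be driven (and checked) directly. For every bin \eqn{k}
#' of a multi-bin gene, the bin's log2 fold change \eqn{\hat\beta_k} is
#' compared to the precision-weighted average \eqn{\hat B_k} of the other
#' bins of the same gene, \eqn{\hat C_k = \hat\beta_k - \hat B_k}.
#'
#' \code{method = "diffSplice"} is the classical statistic: weights
#' \eqn{w_i = 1/u_i^2}; the residual variances of a gene's bins are averaged
#' and the gene-level values squeezed (empirical Bayes), giving a common
#' posterior \eqn{s_g^2} per gene; \eqn{\hat C_k} is rescaled to
#' \eqn{\hat D_k = \hat C_k \sqrt{1 - w_k/\sum_i w_i}} and
#' \eqn{t_k = \hat D_k/(u_k s_g)}.
#'
#' \code{method = "diffSplice2"} drops the constant-variance assumption:
#' bin-level residual variances are squeezed directly into posteriors
#' \eqn{s_i^2}; the weights become \eqn{w_i = 1/(s_i^2 u_i^2)}; and the
#' unscaled \eqn{\hat C_k} is used directly, \eqn{t_k = \hat C_k/(u_k s_k)}.
#'
#' Two-sided p-values use a t distribution with moderated degrees of freedom
#' (residual df plus prior df, capped at the total residual df).
#'
#' @param beta per-bin log2 fold changes (tested coefficient).
#' @param u per-bin unscaled standard deviations (sqrt of the tested diagonal
#'   element of \eqn{(X^T V X)^{-1}}).
#' @param sigma2 per-bin residual variances.
#' @param df per-bin residual degrees of freedom.
#' @param gene per-bin gene ids.
#' @param method \code{"diffSplice2"} (default) or \code{"diffSplice"}.
#' @param robust robust empirical-Bayes prior estimation.
#' @return A \code{data.frame} aligned with the input, with columns
#'   \code{gene}, \code{beta}, \code{u}, \code{B}, \code{C}, \code{D},
#'   \code{t}, \code{df.total}, \code{p.value} (all statistics \code{NA} for
#'   bins of single-bin genes or bins with \code{u = 0}), and attribute
#'   \code{prior} (d0 and s0^2 of the squeeze).
#' @export
binUsageStats <- function(beta, u, sigma2, df, gene,
                          method = c("diffSplice2", "diffSplice"),
                          robust = FALSE) {
    method <- match.arg(method)
    gene <- as.character(gene)
    n <- length(beta)
    stopifnot(length(u) == n, length(sigma2) == n, length(gene) == n)
    df <- rep_len(df, n)
    out <- data.frame(gene = gene, beta = beta, u = u,
                      B = NA_real_, C = NA_real_, D = NA_real_,
                      t = NA_real_, df.total = NA_real_, p.value = NA_real_)

    usable <- u > 0 & is.finite(beta) & is.finite(u)
    if (any(!usable & is.finite(u) & u == 0))
        warning("bin(s) with zero unscaled standard deviation excluded")
    nPerGene <- ave(as.numeric(usable), gene, FUN = sum)
    keep <- usable & nPerGene >= 2

    if (method == "diffSplice") {
        sq <- squeezeVariances(sigma2[usable], df[usable], perBin = FALSE,
                               gene = gene[usable], robust = robust)
        s2post <- sq$var.post[gene]            # per-gene posterior, per bin
        w <- 1 / u^2
        geneDf <- sq$df[gene]
        dfTotal <- geneDf + sq$df.prior
        dfTotal <- pmin(dfTotal, sum(sq$df[unique(gene[keep])]))
    } else {
        sq <- squeezeVariances(sigma2[usable], df[usable], perBin = TRUE,
                               robust = robust)
        s2post <- rep(NA_real_, n)
        s2post[usable] <- sq$var.post
        w <- 1 / (s2post * u^2)
        dfTotal <- df + sq$df.prior
        dfTotal <- pmin(dfTotal, sum(df[keep]))
    }

    idx <- which(keep)
    if (length(idx)) {
        g <- gene[idx]
        S0 <- rowsum(w[idx], g, reorder = FALSE)[, 1]
        S1 <- rowsum(w[idx] * beta[idx], g, reorder = FALSE)[, 1]
        B <- (S1[g] - w[idx] * beta[idx]) / (S0[g] - w[idx])
        C <- beta[idx] - B
        D <- C * sqrt(1 - w[idx] / S0[g])
        out$B[idx] <- B
        out$C[idx] <- C
        out$D[idx] <- D
        if (method == "diffSplice") {
            out$t[idx] <- D / (u[idx] * sqrt(s2post[idx]))
        } else {
            out$t[idx] <- C / (u[idx] * sqrt(s2post[idx]))
        }
        out$df.total[idx] <- dfTotal[idx]
        out$p.value[idx] <- 2 * pt(abs(out$t[idx]), df = dfTotal[idx],
                                   lower.tail = FALSE)
    }
    attr(out, "prior") <- list(df.prior = sq$df.prior,
                               var.prior = sq$var.prior,
                               level = sq$level)
    attr(out, "method") <- method
    out
}

#' Simes aggregation of bin p-values to genes
#'
#' For each gene with sorted p-values \eqn{p_{(1)} \le \dots \le p_{(n)}},
#' the gene-level p-value is \eqn{\min_i n\,p_{(i)}/i}, capped at 1.
#' \code{NA} p-values are dropped; genes with no finite p-value are excluded.
#'
#' @param p bin-level p-values.
#' @param gene per-bin gene ids.
#' @return A named numeric vector of gene-level p-values.
#' @export
simesAggregate <- function(p, gene) {
    gene <- as.character(gene)
    ok <- is.finite(p)
    sp <- split(p[ok], gene[ok])
    sp <- sp[lengths(sp) > 0]
    vapply(sp, function(x) {
        x <- sort(x)
        min(1, min(length(x) * x / seq_along(x)))
    }, numeric(1))
}

#' Differential bin usage analysis
#'
#' Runs the full statistical chain on a \code{\link{BinnedCounts}} object
#' (or a precomputed \code{BinFit}): expression filtering, TMM
#' normalization, voom precision weights, per-bin weighted least squares,
#' and the bin-vs-gene moderated t-test (\code{\link{binUsageStats}}),
#' followed by Benjamini-Hochberg adjustment of the tested bins and Simes
#' aggregation to gene level. Results are written back into the object:
#' \code{rowData} gains \code{bin.coef} (the relative log2 fold change
#' \eqn{\hat C}), \code{bin.t}, \code{bin.p}, \code{bin.FDR} and
#' \code{aveLogExpr}; \code{metadata(x)$geneLevel} holds the gene table
#' (Simes p, FDR, number of tested bins).
#'
#' Genes with exactly one tested bin are reported with \code{NA} bin
#' statistics rather than dropped silently.
#'
#' @param object a \code{BinnedCounts} or a \code{BinFit}.
#' @param design design matrix; defaults to a two-group design from the
#'   condition labels.
#' @param method \code{"diffSplice2"} (default) or \code{"diffSplice"}.
#' @param coef design coefficient to test (default: last column).
#' @param robust robust empirical-Bayes estimation.
#' @return The filtered \code{BinnedCounts} with results attached.
#' @export
diffSpliceBins <- function(object, design = NULL,
                           method = c("diffSplice2", "diffSplice"),
                           coef = NULL, robust = FALSE) {
    method <- match.arg(method)
    bf <- if (inherits(object, "BinFit")) object
          else fitBins(object, design = design, coef = coef)
    fit <- bf$fit
    x <- bf$counts
    res <- binUsageStats(beta = fit$coefficients[, bf$coef],
                         u = fit$stdev.unscaled[, bf$coef],
                         sigma2 = fit$sigma^2, df = fit$df.residual,
                         gene = geneIds(x), method = method, robust = robust)
    rowData(x)$bin.coef <- res$C
    rowData(x)$bin.t <- res$t
    rowData(x)$bin.p <- res$p.value
    rowData(x)$bin.FDR <- NA_real_
    tested <- is.finite(res$p.value)
    rowData(x)$bin.FDR[tested] <- p.adjust(res$p.value[tested], "BH")
    rowData(x)$aveLogExpr <- rowMeans(bf$elist$E)
    gp <- simesAggregate(res$p.value, res$gene)
    geneTab <- DataFrame(gene = names(gp), p.value = unname(gp),
                         FDR = p.adjust(unname(gp), "BH"),
                         nBins = as.integer(table(res$gene[tested])[names(gp)]))
    metadata(x)$geneLevel <- geneTab
    metadata(x)$method <- method
    metadata(x)$prior <- attr(res, "prior")
    metadata(x)$design <- bf$design
    metadata(x)$coef <- bf$coef
    x
}

#' UTR-restricted gene-level results
#'
#' Recomputes the gene-level Simes aggregation after setting the p-values of
#' all bins whose type is not among \code{types} to 1, so that gene-level
#' significance reflects only (3') UTR bins. A gene with no UTR bin gets a
#' gene p-value of 1. Since p-values only move up, the masked Simes p-value
#' can never be smaller than the unmasked one.
#'
#' @param object output of \code{\link{diffSpliceBins}}.
#' @param types bin types retained for aggregation (default UTR and 3' UTR).
#' @return The object with \code{metadata(x)$geneLevelUtr} added.
#' @export
utrGeneResults <- function(object, types = c("UTR", "3UTR")) {
    p <- rowData(object)$bin.p
    if (is.null(p)) stop("run diffSpliceBins() first")
    masked <- p
    keepType <- binTypes(object) %in% types
    masked[!keepType & is.finite(p)] <- 1
    gp <- simesAggregate(masked, geneIds(object))
    nUtr <- rowsum(as.numeric(keepType & is.finite(p)),
                   as.character(geneIds(object)), reorder = FALSE)[, 1]
    geneTab <- DataFrame(gene = names(gp), p.value = unname(gp),
                         FDR = p.adjust(unname(gp), "BH"),
                         nUtrBins = as.integer(nUtr[names(gp)]))
    metadata(object)$geneLevelUtr <- geneTab
    metadata(object)$utrTypes <- types
    object
}

#' Gene-level results accessor
#'
#' @param object output of \code{\link{diffSpliceBins}} (and, for
#'   \code{utr = TRUE}, \code{\link{utrGeneResults}}).
#' @param utr return the UTR-restricted table.
#' @return A \code{DataFrame} of gene-level results.
#' @export
geneLevelResults <- function(object, utr = FALSE) {
    tab <- if (utr) metadata(object)$geneLevelUtr
           else metadata(object)$geneLevel
    if (is.null(tab))
        stop("no gene-level results; run diffSpliceBins()",
             if (utr) " and utrGeneResults()" else "")
    tab
}

#' Gene-level effect-size scores
#'
#' Summarizes per-bin relative fold changes into one score per gene, for
#' ranking and plotting. With significance weights
#' \eqn{\omega_k = \min(-\log_{10} p_k, \mathrm{cap})}:
#' \itemize{
#' \item \code{mode = "DEU"}: \eqn{\sum_k |\hat C_k| \omega_k / \sum_k
#'   \omega_k} over all tested bins (absolute coefficients weighted by
#'   significance);
#' \item \code{mode = "UTR"}: \eqn{\sum_k \hat C_k\, w_k^{kb}\, \omega_k /
#'   \sum_k \omega_k} over UTR-type bins, where \eqn{w_k^{kb}} is the bin
#'   width in kilobases (signed coefficients weighted by size and
#'   significance, so positive scores indicate 3' UTR lengthening).
#' }
#' Genes whose bins all have \eqn{p = 1} (zero weight) score 0.
#'
#' @param object output of \code{\link{diffSpliceBins}}.
#' @param mode \code{"UTR"} (default) or \code{"DEU"}.
#' @param cap cap on the per-bin significance weight \eqn{-\log_{10} p}.
#' @param types bin types used in UTR mode.
#' @param sig.FDR bin FDR threshold defining "significant" bins for the
#'   reported relative expression.
#' @return A \code{DataFrame}: gene, score, gene p/FDR, mean log expression,
#'   relative expression of significant bins.
#' @export
geneEffectScores <- function(object, mode = c("UTR", "DEU"), cap = 10,
                             types = c("UTR", "3UTR"), sig.FDR = 0.05) {
    mode <- match.arg(mode)
    p <- rowData(object)$bin.p
    C <- rowData(object)$bin.coef
    if (is.null(p)) stop("run diffSpliceBins() first")
    gene <- as.character(geneIds(object))
    use <- is.finite(p) & is.finite(C)
    if (mode == "UTR") use <- use & binTypes(object) %in% types
    om <- pmin(-log10(pmax(p, 1e-300)), cap)
    contrib <- if (mode == "UTR") C * (width(rowRanges(object)) / 1000) * om
               else abs(C) * om
    num <- rowsum(ifelse(use, contrib, 0), gene, reorder = FALSE)[, 1]
    den <- rowsum(ifelse(use, om, 0), gene, reorder = FALSE)[, 1]
    score <- ifelse(den > 0, num / den, 0)
    gl <- if (mode == "UTR" && !is.null(metadata(object)$geneLevelUtr))
        metadata(object)$geneLevelUtr else metadata(object)$geneLevel
    m <- match(names(score), gl$gene)
    ave <- rowData(object)$aveLogExpr
    meanExpr <- rowsum(ave, gene, reorder = FALSE)[, 1] /
        rowsum(rep(1, length(gene)), gene, reorder = FALSE)[, 1]
    cpm <- t(t(binCounts(object) + 0.5) /
                 (libSizes(object) * normFactors(object) + 1)) * 1e6
    binExpr <- rowMeans(cpm)
    sig <- is.finite(rowData(object)$bin.FDR) &
        rowData(object)$bin.FDR < sig.FDR
    relSig <- rowsum(ifelse(sig, binExpr, 0), gene, reorder = FALSE)[, 1] /
        rowsum(binExpr, gene, reorder = FALSE)[, 1]
    DataFrame(gene = names(score), score = unname(score),
              p.value = gl$p.value[m], FDR = gl$FDR[m],
              meanLogExpr = unname(meanExpr),
              relExprSignif = unname(relSig))
}

#' Top genes by differential usage
#'
#' @param object output of \code{\link{diffSpliceBins}} (run
#'   \code{\link{utrGeneResults}} first for UTR mode).
#' @param mode \code{"UTR"} or \code{"DEU"}.
#' @param n number of genes to return.
#' @param ... passed to \code{\link{geneEffectScores}}.
#' @return A \code{DataFrame} sorted by gene p-value.
#' @export
topGenes <- function(object, mode = c("UTR", "DEU"), n = 20, ...) {
    mode <- match.arg(mode)
    sc <- geneEffectScores(object, mode = mode, ...)
    sc <- sc[order(sc$p.value, -abs(sc$score)), ]
    head(sc, n)
}

#' Per-gene bin report (plot-ready)
#'
#' Emits, for every tested bin, its coordinates, type, per-sample normalized
#' counts (CPM on effective library sizes) and statistics: the tabular
#' substrate for bin-level plots and heatmaps.
#'
#' @param object output of \code{\link{diffSpliceBins}}.
#' @return A \code{data.frame}.
#' @export
binReport <- function(object) {
    cpm <- round(t(t(binCounts(object)) /
                       (libSizes(object) * normFactors(object))) * 1e6, 4)
    colnames(cpm) <- paste0("cpm.", colnames(object))
    data.frame(bin = rownames(object),
               chrom = as.character(seqnames(rowRanges(object))),
               start = start(rowRanges(object)), end = end(rowRanges(object)),
               strand = as.character(strand(rowRanges(object))),
               gene = geneIds(object), type = binTypes(object),
               width = width(rowRanges(object)),
               coef = rowData(object)$bin.coef, t = rowData(object)$bin.t,
               p.value = rowData(object)$bin.p, FDR = rowData(object)$bin.FDR,
               cpm, check.names = FALSE)
}
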