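simpleBc <- function(counts, cond = rep(c("A", "B"), each = 3)) {
    n <- nrow(counts)
    bins <- GRanges("chr1", IRanges(seq_len(n) * 1000, width = 100),
                    strand = "+")
    mcols(bins)$gene <- paste0("g", ceiling(seq_len(n) / 2))
    mcols(bins)$type <- "CDS"
    names(bins) <- binIds <- paste0(mcols(bins)$gene, ":",
                                    ave(seq_len(n), mcols(bins)$gene,
                                        FUN = seq_along))
    BinnedCounts(counts, bins, condition = cond)
}

test_that("expression filter keeps bins per the smallest-group CPM rule", {
    set.seed(1)
    filler <- matrix(rpois(198 * 6, 5000), 198, 6)   # sets library size ~1e6
    target <- rbind(rep(0, 6),                        # all-zero: removed
                    c(12, 12, 12, 0, 0, 0),           # >=10 CPM-ish in 3 of 3v3
                    c(3, 3, 3, 1, 1, 1),              # too low everywhere
                    rep(5000, 6))                     # abundant: kept
    cnt <- rbind(target, filler)
    bc <- simpleBc(cnt)
    kept <- rownames(filterBins(bc))
    expect_false(rownames(bc)[1] %in% kept)
    expect_true(rownames(bc)[2] %in% kept)
    expect_false(rownames(bc)[3] %in% kept)
    expect_true(rownames(bc)[4] %in% kept)
    expect_error(filterBins(bc, min.count = 1e9), "no bin passes")
})

test_that("TMM factors: symmetric inputs give unit factors multiplying to 1", {
    set.seed(2)
    base <- matrix(rpois(600, 100), 100, 6)
    bc <- tmmNormFactors(simpleBc(cbind(base[, 1], base[, 1], base)[, 1:6]))
    same <- tmmNormFactors(simpleBc(base[, c(1, 1, 1, 1, 1, 1)]))
    expect_equal(unname(normFactors(same)), rep(1, 6))
    # uniform x2 scaling is absorbed by the library size (equality is exact
    # only in the continuous limit: the deeper copy gets halved
    # inverse-variance weights against the reference library)
    scaled <- cbind(base[, 1], base[, 1] * 2L, base[, 2:5])
    nf <- normFactors(tmmNormFactors(simpleBc(scaled)))
    expect_equal(unname(nf[1]), unname(nf[2]), tolerance = 0.01)
    expect_equal(unname(nf[1]), 1, tolerance = 0.01)
    # factors always multiply to one
    rnd <- simpleBc(matrix(rpois(600, rlnorm(600, 4, 1)), 100, 6))
    expect_equal(prod(normFactors(tmmNormFactors(rnd))), 1, tolerance = 1e-12)
})

test_that("voom weights: symmetric inputs give equal weights; trend is monotone", {
    # exchangeable rows: weights are strictly positive and depend on the
    # fitted count only through the common trend
    set.seed(30)
    cnt <- matrix(rpois(360, 200L), 60, 6)
    bc <- tmmNormFactors(simpleBc(cnt))
    v <- voomWeights(bc)
    expect_true(all(v$weights > 0))

    # relabeling samples within a group leaves weights unchanged
    set.seed(3)
    cnt2 <- matrix(rpois(600, rep(rlnorm(100, 5, 1), 6)), 100, 6)
    bc2 <- tmmNormFactors(simpleBc(cnt2))
    v1 <- voomWeights(bc2)
    bc3 <- bc2[, c(2, 1, 3, 4, 6, 5)]
    colData(bc3)$condition <- conditions(bc2)
    v2 <- voomWeights(bc3)
    expect_equal(v1$weights[, c(2, 1, 3, 4, 6, 5)], v2$weights,
                 tolerance = 1e-10, ignore_attr = TRUE)

    # larger fitted counts get larger weights along the decreasing trend:
    # compare against an independent rank correlation of fitted log-count
    # vs weight
    fitc <- rowMeans(v1$E)
    expect_gt(cor(fitc, rowMeans(v1$weights), method = "spearman"), 0.8)
})

test_that("weighted least squares matches closed forms and a direct solve", {
    # two-group design, unit weights: beta = difference of group means
    y <- matrix(c(1, 2, 3, 7, 8, 9), 1)
    design <- cbind(Int = 1, grp = rep(0:1, each = 3))
    el <- new("EList", list(E = y, weights = matrix(1, 1, 6)))
    fit <- fitBinModels(el, design)
    expect_equal(unname(fit$coefficients[1, "grp"]), 6)

    # duplicating every sample leaves beta, halves u^2
    el2 <- new("EList", list(E = cbind(y, y), weights = matrix(1, 1, 12)))
    fit2 <- fitBinModels(el2, rbind(design, design))
    expect_equal(fit2$coefficients, fit$coefficients)
    expect_equal(fit2$stdev.unscaled^2, fit$stdev.unscaled^2 / 2)

    # zero-variance bin: exact coefficient, zero residual variance
    y0 <- matrix(rep(c(2, 5), each = 3), 1)
    f0 <- fitBinModels(new("EList", list(E = y0, weights = matrix(1, 1, 6))),
                       design)
    expect_equal(unname(f0$coefficients[1, "grp"]), 3)
    expect_equal(unname(f0$sigma), 0)

    # WLS oracle: random 5x3 systems against the normal equations
    set.seed(4)
    for (rep in 1:20) {
        X <- cbind(1, matrix(rnorm(10), 5, 2))
        yv <- rnorm(5)
        w <- runif(5, 0.2, 3)
        fit <- fitBinModels(new("EList", list(E = matrix(yv, 1),
                                              weights = matrix(w, 1))), X)
        V <- diag(w)
        betaRef <- solve(t(X) %*% V %*% X, t(X) %*% V %*% yv)
        uRef <- sqrt(diag(solve(t(X) %*% V %*% X)))
        expect_equal(unname(fit$coefficients[1, ]), drop(betaRef),
                     tolerance = 1e-10, ignore_attr = TRUE)
        expect_equal(unname(fit$stdev.unscaled[1, ]), uRef,
                     tolerance = 1e-10, ignore_attr = TRUE)
    }
    expect_error(fitBinModels(el, cbind(1, c(1, 1, 1, 0, 0, 0),
                                        c(0, 0, 0, 1, 1, 1))),
                 "rank-deficient")
})

test_that("variance squeezing is a convex combination with a recoverable prior", {
    # identical variances: posteriors equal the common value
    sq <- squeezeVariances(rep(2, 50), df = 4)
    expect_equal(sq$var.post, rep(2, 50))

    # prior recovery on variances from a scaled inverse-chi^2 prior
    set.seed(6)
    d0 <- 4; s02 <- 2; d <- 5
    true <- d0 * s02 / rchisq(500, d0)
    obs <- true * rchisq(500, d) / d
    sq3 <- squeezeVariances(obs, df = d)
    expect_lt(abs(sq3$df.prior - d0) / d0, 0.25)
    expect_lt(abs(sq3$var.prior - s02) / s02, 0.25)

    # posteriors lie between the sample variance and the prior, and follow
    # the convex combination
    lo <- pmin(obs, sq3$var.prior); hi <- pmax(obs, sq3$var.prior)
    expect_true(all(sq3$var.post >= lo - 1e-12 & sq3$var.post <= hi + 1e-12))
    expect_equal(sq3$var.post,
                 (sq3$df.prior * sq3$var.prior + d * obs) /
                     (sq3$df.prior + d),
                 tolerance = 1e-8)

    # legacy path: gene averaging then squeezing
    gene <- rep(c("a", "b"), each = 250)
    sqg <- squeezeVariances(obs, df = d, perBin = FALSE, gene = gene)
    expect_equal(sqg$level, "gene")
    expect_equal(length(sqg$var.post), 2L)
    ref <- limma::squeezeVar(as.numeric(tapply(obs, gene, mean)),
                             as.numeric(tapply(rep(d, 500), gene, sum)))
    expect_equal(as.numeric(sqg$var.post), as.numeric(ref$var.post))
})
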