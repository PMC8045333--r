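# Brute-force reference for the bin-vs-gene statistics: explicit per-gene
# loops over the defining formulas, independent of the vectorized engine.
oracleBinStats <- function(beta, u, s2, df, gene, method) {
    gene <- as.character(gene)
    genes <- unique(gene)
    n <- length(beta)
    out <- data.frame(B = rep(NA_real_, n), C = NA_real_, D = NA_real_,
                      t = NA_real_, p.value = NA_real_)
    if (method == "diffSplice") {
        gm <- vapply(genes, function(g) mean(s2[gene == g]), 0)
        gdf <- vapply(genes, function(g) sum(df[gene == g]), 0)
        sq <- limma::squeezeVar(gm, gdf)
        multi <- genes[vapply(genes, function(g) sum(gene == g), 0) >= 2]
        cap <- sum(gdf[match(multi, genes)])
        for (g in multi) {
            idx <- which(gene == g)
            w <- 1 / u[idx]^2
            sg <- sqrt(sq$var.post[match(g, genes)])
            dft <- min(gdf[match(g, genes)] + sq$df.prior, cap)
            for (j in seq_along(idx)) {
                k <- idx[j]
                B <- sum(w[-j] * beta[idx][-j]) / sum(w[-j])
                C <- beta[k] - B
                D <- C * sqrt(1 - w[j] / sum(w))
                t <- D / (u[k] * sg)
                out[k, ] <- c(B, C, D, t, 2 * pt(abs(t), dft, lower.tail = FALSE))
            }
        }
    } else {
        sq <- limma::squeezeVar(s2, df)
        s2p <- sq$var.post
        multi <- genes[vapply(genes, function(g) sum(gene == g), 0) >= 2]
        cap <- sum(df[gene %in% multi])
        for (g in multi) {
            idx <- which(gene == g)
            w <- 1 / (s2p[idx] * u[idx]^2)
            for (j in seq_along(idx)) {
                k <- idx[j]
                B <- sum(w[-j] * beta[idx][-j]) / sum(w[-j])
                C <- beta[k] - B
                t <- C / (u[k] * sqrt(s2p[k]))
                dft <- min(df[k] + sq$df.prior, cap)
                out[k, c("B", "C", "t", "p.value")] <-
                    c(B, C, t, 2 * pt(abs(t), dft, lower.tail = FALSE))
                out$D[k] <- C * sqrt(1 - w[j] / sum(w))
            }
        }
    }
    out
}

# random per-bin fit summaries for ng small genes
randomFitSummaries <- function(ng, seed) {
    set.seed(seed)
    nb <- sample(2:6, ng, replace = TRUE)
    gene <- rep(sprintf("g%03d", seq_len(ng)), nb)
    n <- length(gene)
    list(beta = rnorm(n), u = runif(n, 0.2, 2),
         s2 = rchisq(n, 4) / 4, df = rep(4, n), gene = gene)
}
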