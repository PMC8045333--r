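#' Write a deterministic toy annotation and APA site set
#'
#' Produces a small multi-chromosome GTF plus a matching poly(A)-site BED
#' covering every bin-construction edge case: flattening of partially
#' overlapping exons, UTR/3' UTR/non-coding labeling (including a
#' coding-by-biotype transcript without CDS records), an APA site splitting
#' an existing 3' UTR bin, a chain of downstream APA extensions, a
#' minus-strand extension, and (by flag) a multi-gene overlap, a site beyond
#' \code{maxUTRbinSize}, and a site whose nearest upstream feature is the
#' start of the next gene.
#'
#' @param dir output directory (created if needed).
#' @param overlappingGenes include two genes sharing an exonic interval.
#' @param farApa include a site 20 kb downstream of its gene (dropped under
#'   the default 15 kb limit).
#' @param geneStartGuard include a site separated from the previous gene by a
#'   gene start (dropped by the guard).
#' @return A list with paths \code{gtf} and \code{bed}.
#' @export
makeToyAnnotation <- function(dir = tempfile("toyann"),
                              overlappingGenes = TRUE, farApa = TRUE,
                              geneStartGuard = TRUE) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    A <- function(gene, tx = NULL, gb = "protein_coding", tb = gb) {
        a <- sprintf('gene_id "%s"; gene_biotype "%s";', gene, gb)
        if (!is.null(tx))
            a <- paste(a, sprintf('transcript_id "%s"; transcript_biotype "%s";',
                                  tx, tb))
        a
    }
    L <- function(chr, src, feat, s, e, strand, attr)
        paste(chr, src, feat, s, e, ".", strand, ".", attr, sep = "\t")
    g <- c(
        ## gene1 (+): two transcripts, partial exon overlap, CDS, biotype-only
        ## coding transcript (tx2 has no CDS records)
        L("chr1", "toy", "gene", 101, 600, "+", A("gene1")),
        L("chr1", "toy", "transcript", 101, 600, "+", A("gene1", "tx1")),
        L("chr1", "toy", "exon", 101, 200, "+", A("gene1", "tx1")),
        L("chr1", "toy", "exon", 301, 400, "+", A("gene1", "tx1")),
        L("chr1", "toy", "exon", 501, 600, "+", A("gene1", "tx1")),
        L("chr1", "toy", "CDS", 151, 200, "+", A("gene1", "tx1")),
        L("chr1", "toy", "CDS", 301, 350, "+", A("gene1", "tx1")),
        L("chr1", "toy", "transcript", 101, 450, "+", A("gene1", "tx2")),
        L("chr1", "toy", "exon", 101, 200, "+", A("gene1", "tx2")),
        L("chr1", "toy", "exon", 301, 450, "+", A("gene1", "tx2")),
        ## gene2 (-): 3' UTR at the low-coordinate end
        L("chr1", "toy", "gene", 5001, 6000, "-", A("gene2")),
        L("chr1", "toy", "transcript", 5201, 6000, "-", A("gene2", "tx3")),
        L("chr1", "toy", "exon", 5201, 5400, "-", A("gene2", "tx3")),
        L("chr1", "toy", "exon", 5401, 6000, "-", A("gene2", "tx3")),
        L("chr1", "toy", "CDS", 5401, 5900, "-", A("gene2", "tx3")),
        ## gene3: non-coding
        L("chr1", "toy", "gene", 8001, 8500, "+", A("gene3", gb = "lncRNA")),
        L("chr1", "toy", "transcript", 8001, 8500, "+",
          A("gene3", "tx4", gb = "lncRNA")),
        L("chr1", "toy", "exon", 8001, 8500, "+",
          A("gene3", "tx4", gb = "lncRNA")))
    if (overlappingGenes) g <- c(g,
        L("chr1", "toy", "gene", 20001, 20100, "+", A("geneA", gb = "lncRNA")),
        L("chr1", "toy", "transcript", 20001, 20100, "+",
          A("geneA", "tx5", gb = "lncRNA")),
        L("chr1", "toy", "exon", 20001, 20100, "+",
          A("geneA", "tx5", gb = "lncRNA")),
        L("chr1", "toy", "gene", 20051, 20150, "+", A("geneB", gb = "lncRNA")),
        L("chr1", "toy", "transcript", 20051, 20150, "+",
          A("geneB", "tx6", gb = "lncRNA")),
        L("chr1", "toy", "exon", 20051, 20150, "+",
          A("geneB", "tx6", gb = "lncRNA")))
    if (farApa) g <- c(g,
        L("chr2", "toy", "gene", 101, 1000, "+", A("gene4")),
        L("chr2", "toy", "transcript", 101, 1000, "+", A("gene4", "tx7")),
        L("chr2", "toy", "exon", 101, 1000, "+", A("gene4", "tx7")),
        L("chr2", "toy", "CDS", 201, 800, "+", A("gene4", "tx7")))
    if (geneStartGuard) g <- c(g,
        L("chr3", "toy", "gene", 101, 1000, "+", A("gene5")),
        L("chr3", "toy", "transcript", 101, 1000, "+", A("gene5", "tx8")),
        L("chr3", "toy", "exon", 101, 1000, "+", A("gene5", "tx8")),
        L("chr3", "toy", "CDS", 201, 900, "+", A("gene5", "tx8")),
        L("chr3", "toy", "gene", 1300, 2000, "+", A("gene6")),
        L("chr3", "toy", "transcript", 1450, 2000, "+", A("gene6", "tx9")),
        L("chr3", "toy", "exon", 1450, 2000, "+", A("gene6", "tx9")),
        L("chr3", "toy", "CDS", 1500, 1900, "+", A("gene6", "tx9")))
    gtf <- file.path(dir, "toy.gtf")
    writeLines(g, gtf)

    # BED is 0-based half-open; single-base sites
    bedLine <- function(chr, pos1, name, strand)
        paste(chr, pos1 - 1L, pos1, name, 0, strand, sep = "\t")
    b <- c(bedLine("chr1", 550, "split_site", "+"),
           bedLine("chr1", 800, "apa_next", "+"),
           bedLine("chr1", 1000, "apa_second", "+"),
           bedLine("chr1", 1200, "apa_third", "+"),
           bedLine("chr1", 5000, "apa_minus", "-"))
    if (farApa) b <- c(b, bedLine("chr2", 21000, "apa_far", "+"))
    if (geneStartGuard) b <- c(b, bedLine("chr3", 1400, "apa_guarded", "+"))
    bed <- file.path(dir, "toy_apa.bed")
    writeLines(b, bed)
    list(gtf = gtf, bed = bed)
}

#' Build a SAM read fixture with an analytically known count matrix
#'
#' Emits single-end reads over a bin set according to a plan: reads fully
#' inside one bin, junction reads spanning two genomically adjacent bins,
#' spliced reads whose intron gap skips the intervening bin, and off-bin
#' reads that contribute only to the library size. The expected per-bin
#' counts (each read counted once per overlapped bin; spliced gaps do not
#' count) are computed alongside.
#'
#' @param bins a bin \code{GRanges}.
#' @param plan a data.frame with columns \code{kind} (\code{"interior"},
#'   \code{"junction"} = bins \code{bin}, \code{bin + 1};
#'   \code{"spliced"} = blocks in bins \code{bin} and \code{bin + 2},
#'   gap over \code{bin + 1}; \code{"offbin"}), \code{bin} (index into
#'   \code{bins}; ignored for offbin) and \code{n} (number of reads).
#' @return A list: \code{sam} (character vector of SAM lines),
#'   \code{expected} (named expected count vector), \code{nReads}.
#' @export
makeReadFixture <- function(bins, plan) {
    chrLen <- tapply(end(bins), as.character(seqnames(bins)), max) + 5000L
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", names(chrLen), chrLen))
    expected <- setNames(integer(length(bins)), names(bins))
    reads <- character(0)
    rid <- 0L
    emit <- function(chr, pos, cigar) {
        rid <<- rid + 1L
        mlen <- sum(as.integer(regmatches(cigar,
            gregexpr("[0-9]+(?=[M=X])", cigar, perl = TRUE))[[1]]))
        paste(sprintf("read%03d", rid), 0, chr, pos, 60, cigar, "*", 0, 0,
              strrep("A", mlen), "*", sep = "\t")
    }
    for (r in seq_len(nrow(plan))) {
        kind <- plan$kind[r]; i <- plan$bin[r]; n <- plan$n[r]
        for (dup in seq_len(n)) {
            if (kind == "interior") {
                len <- min(width(bins)[i], 30L)
                reads <- c(reads, emit(as.character(seqnames(bins))[i],
                                       start(bins)[i], paste0(len, "M")))
                expected[i] <- expected[i] + 1L
            } else if (kind == "junction") {
                stopifnot(end(bins)[i] + 1L == start(bins)[i + 1])
                reads <- c(reads, emit(as.character(seqnames(bins))[i],
                                       end(bins)[i] - 9L, "20M"))
                expected[i] <- expected[i] + 1L
                expected[i + 1] <- expected[i + 1] + 1L
            } else if (kind == "spliced") {
                gap <- start(bins)[i + 2] - end(bins)[i] - 1L
                stopifnot(gap > 0)
                reads <- c(reads, emit(as.character(seqnames(bins))[i],
                                       end(bins)[i] - 9L,
                                       paste0("10M", gap, "N10M")))
                expected[i] <- expected[i] + 1L
                expected[i + 2] <- expected[i + 2] + 1L
            } else if (kind == "offbin") {
                chr <- as.character(seqnames(bins))[1]
                reads <- c(reads, emit(chr, chrLen[chr] - 100L, "30M"))
            } else stop("unknown read kind: ", kind)
        }
    }
    list(sam = c(header, reads), expected = expected, nReads = rid)
}

#' Simulate bin counts with known differential 3' UTR usage
#'
#' Count-level emulation of a two-condition RNA-seq experiment in which a
#' subset of genes expresses a pair of isoforms differing only in 3' UTR
#' length. Each gene consists of CDS bins, one shared 3' UTR bin and, for
#' UTR-change genes, 1-3 distal 3' UTR segments (the next, second next or
#' third next downstream poly(A) segment) included only in the long isoform.
#' Both isoforms start at equal abundance; in condition 2 of a UTR-change
#' gene one isoform is up- and the other down-regulated by the same fold
#' change sampled uniformly between 1.3 and 5 (lengthening or shortening at
#' random), so shared bins shift by \eqn{(f + 1/f)/2} while long-only bins
#' shift by \eqn{f}. Additional genes receive a whole-gene fold change with
#' no usage shift, both within and outside the UTR-change set. Counts are
#' drawn from a negative binomial with the configured dispersion around the
#' analytic isoform-mixture means.
#'
#' @param nGenes total number of genes.
#' @param nUtrGenes genes with a differential-UTR pair.
#' @param nDeUtrGenes UTR-change genes additionally given whole-gene DE.
#' @param nDeOtherGenes non-UTR genes given whole-gene DE.
#' @param binsPerGene range (min, max) of bins per gene.
#' @param foldChangeRange isoform fold-change range (linear scale).
#' @param deFoldChangeRange whole-gene fold-change range.
#' @param extensionChoices how many distal segments the long isoform may add.
#' @param repsPerCondition replicates per condition.
#' @param dispersion negative-binomial dispersion (1/size).
#' @param meanLog,meanSdLog log-normal parameters of baseline bin means.
#' @param seed random seed (set internally for reproducibility).
#' @return A list: \code{counts} (a \code{\link{BinnedCounts}} with condition
#'   labels and the latent mean matrices in \code{metadata()$mu}) and
#'   \code{truth} (per-gene DataFrame: UTR change, direction, fold changes,
#'   affected bin ids).
#' @export
simulateUtrCounts <- function(nGenes = 500, nUtrGenes = 100,
                              nDeUtrGenes = NULL, nDeOtherGenes = NULL,
                              binsPerGene = c(4, 8),
                              foldChangeRange = c(1.3, 5),
                              deFoldChangeRange = c(1.3, 5),
                              extensionChoices = 1:3,
                              repsPerCondition = 3, dispersion = 0.1,
                              meanLog = log(150), meanSdLog = 1,
                              seed = NULL) {
    # 30% of UTR-change genes (and as many others) get whole-gene DE,
    # mirroring the 300-per-1000 benchmark design
    if (is.null(nDeUtrGenes)) nDeUtrGenes <- round(0.3 * nUtrGenes)
    if (is.null(nDeOtherGenes))
        nDeOtherGenes <- min(round(0.3 * nUtrGenes), nGenes - nUtrGenes)
    stopifnot(nUtrGenes <= nGenes, nDeUtrGenes <= nUtrGenes,
              nDeOtherGenes <= nGenes - nUtrGenes,
              foldChangeRange[1] > 1)
    if (!is.null(seed)) set.seed(seed)
    geneIdsAll <- sprintf("gene%04d", seq_len(nGenes))
    utrChange <- seq_len(nGenes) <= nUtrGenes
    deGenes <- c(if (nDeUtrGenes > 0) sample(which(utrChange), nDeUtrGenes),
                 if (nDeOtherGenes > 0) sample(which(!utrChange),
                                               nDeOtherGenes))

    rows <- list(); mu1 <- list(); mu2 <- list()
    truth <- data.frame(gene = geneIdsAll, utrChange = utrChange,
                        direction = NA_character_, foldChange = NA_real_,
                        deChange = seq_len(nGenes) %in% deGenes,
                        deFoldChange = NA_real_,
                        affectedBins = NA_character_,
                        stringsAsFactors = FALSE)
    offset <- 0L
    for (gi in seq_len(nGenes)) {
        nb <- sample(seq(binsPerGene[1], binsPerGene[2]), 1)
        ext <- if (utrChange[gi]) sample(extensionChoices, 1) else 0L
        nb <- max(nb, ext + 2L)
        type <- c(rep("CDS", nb - ext - 1L), "3UTR", rep("3UTR", ext))
        longOnly <- c(rep(FALSE, nb - ext), rep(TRUE, ext))
        r <- rlnorm(nb, meanLog, meanSdLog)
        aS1 <- aL1 <- 0.5
        if (utrChange[gi]) {
            f <- runif(1, foldChangeRange[1], foldChangeRange[2])
            dir <- sample(c("lengthen", "shorten"), 1)
            if (dir == "lengthen") { aL2 <- 0.5 * f; aS2 <- 0.5 / f }
            else { aL2 <- 0.5 / f; aS2 <- 0.5 * f }
            truth$direction[gi] <- dir
            truth$foldChange[gi] <- f
        } else { aL2 <- aS2 <- 0.5 }
        m1 <- r * ifelse(longOnly, 2 * aL1, aS1 + aL1)
        m2 <- r * ifelse(longOnly, 2 * aL2, aS2 + aL2)
        if (gi %in% deGenes) {
            d <- runif(1, deFoldChangeRange[1], deFoldChangeRange[2])
            if (sample(c(TRUE, FALSE), 1)) d <- 1 / d
            m2 <- m2 * d
            truth$deFoldChange[gi] <- d
        }
        widths <- round(runif(nb, 100, 2000))
        starts <- offset + cumsum(c(1L, widths[-nb] + 100L))
        rows[[gi]] <- data.frame(start = starts, end = starts + widths - 1L,
                                 gene = geneIdsAll[gi], type = type,
                                 apaDerived = longOnly,
                                 stringsAsFactors = FALSE)
        offset <- starts[nb] + widths[nb] + 1000L
        mu1[[gi]] <- m1; mu2[[gi]] <- m2
        if (utrChange[gi])
            truth$affectedBins[gi] <- paste(
                paste0(geneIdsAll[gi], ":", which(longOnly)), collapse = ",")
    }
    tab <- do.call(rbind, rows)
    bins <- GRanges("sim1", IRanges(tab$start, tab$end), strand = "+")
    mcols(bins)$gene <- tab$gene
    mcols(bins)$type <- tab$type
    mcols(bins)$geneAmbiguous <- FALSE
    mcols(bins)$apaDerived <- tab$apaDerived
    names(bins) <- binIds(bins)
    m1 <- unlist(mu1); m2 <- unlist(mu2)
    nrep <- repsPerCondition
    mu <- cbind(matrix(rep(m1, nrep), ncol = nrep),
                matrix(rep(m2, nrep), ncol = nrep))
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                     nrow = nrow(mu))
    colnames(counts) <- c(paste0("A", seq_len(nrep)), paste0("B", seq_len(nrep)))
    bc <- BinnedCounts(counts, bins,
                       condition = rep(c("A", "B"), each = nrep))
    metadata(bc)$mu <- list(cond1 = m1, cond2 = m2)
    metadata(bc)$simParams <- list(nGenes = nGenes, nUtrGenes = nUtrGenes,
                                   nDeUtrGenes = nDeUtrGenes,
                                   nDeOtherGenes = nDeOtherGenes,
                                   dispersion = dispersion, seed = seed)
    list(counts = bc, truth = truth)
}
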