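suppressPackageStartupMessages({
    library(GenomicRanges)
    library(SummarizedExperiment)
})

# write GTF lines for a simple gene; exL/cdsL are lists of c(start, end)
gtfGene <- function(chr, gene, strand, exL, cdsL = list(), tx = paste0(gene, ".t1"),
                    biotype = "protein_coding", span = NULL) {
    A <- sprintf('gene_id "%s"; gene_biotype "%s"; transcript_id "%s"; transcript_biotype "%s";',
                 gene, biotype, tx, biotype)
    if (is.null(span))
        span <- c(min(vapply(exL, `[`, 0, 1)), max(vapply(exL, `[`, 0, 2)))
    c(paste(chr, "t", "gene", span[1], span[2], ".", strand, ".",
            sprintf('gene_id "%s"; gene_biotype "%s";', gene, biotype),
            sep = "\t"),
      paste(chr, "t", "transcript", min(vapply(exL, `[`, 0, 1)),
            max(vapply(exL, `[`, 0, 2)), ".", strand, ".", A, sep = "\t"),
      vapply(exL, function(e)
          paste(chr, "t", "exon", e[1], e[2], ".", strand, ".", A, sep = "\t"),
          ""),
      if (length(cdsL)) vapply(cdsL, function(e)
          paste(chr, "t", "CDS", e[1], e[2], ".", strand, ".", A, sep = "\t"),
          ""))
}

writeGtf <- function(lines) {
    f <- tempfile(fileext = ".gtf")
    writeLines(lines, f)
    f
}

writeBed <- function(chr, pos, strand) {
    f <- tempfile(fileext = ".bed")
    writeLines(paste(chr, pos - 1L, pos, paste0("s", seq_along(pos)), 0, strand,
                     sep = "\t"), f)
    f
}

binFrame <- function(bins)
    data.frame(chrom = as.character(seqnames(bins)), start = start(bins),
               end = end(bins), strand = as.character(strand(bins)),
               gene = mcols(bins)$gene, type = mcols(bins)$type,
               geneAmbiguous = mcols(bins)$geneAmbiguous,
               apaDerived = mcols(bins)$apaDerived,
               stringsAsFactors = FALSE, row.names = NULL)

# three adjacent bins of one plus-strand gene, for counter fixtures
threeBinGene <- function() {
    bins <- GRanges("chr1", IRanges(c(101, 201, 351), c(200, 350, 500)),
                    strand = "+")
    mcols(bins)$gene <- "g1"
    mcols(bins)$type <- c("CDS", "3UTR", "3UTR")
    mcols(bins)$geneAmbiguous <- FALSE
    mcols(bins)$apaDerived <- FALSE
    names(bins) <- paste0("g1:", 1:3)
    bins
}

writeSam <- function(lines) {
    f <- tempfile(fileext = ".sam")
    writeLines(lines, f)
    f
}

# session-cached expensive fixtures (shared by property and acceptance tests)
.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
    if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
    .cache[[key]]
}

nullSim <- function() cached("nullSim",
    simulateUtrCounts(nGenes = 300, nUtrGenes = 0, nDeUtrGenes = 0,
                      nDeOtherGenes = 0, seed = 42))

benchSim <- function() cached("benchSim", simulateUtrCounts(seed = 7))

benchFit <- function(method) cached(paste0("benchFit.", method),
    utrGeneResults(diffSpliceBins(benchSim()$counts, method = method)))

nullFit <- function(method) cached(paste0("nullFit.", method),
    diffSpliceBins(nullSim()$counts, method = method))
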