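test_that("annotation readback, coding status and validation errors", {
    g <- gtfGene("chr1", "gA", "+", list(c(1, 100), c(201, 300)))
    ann <- readAnnotation(writeGtf(g))
    expect_equal(length(ann$exons), 2L)
    expect_equal(length(ann$cds), 0L)
    # coding by biotype even without CDS records
    expect_true(ann$transcripts$coding)

    g2 <- gtfGene("chr1", "gB", "+", list(c(1, 100)), list(c(21, 80)),
                  biotype = "misc")
    ann2 <- readAnnotation(writeGtf(g2))
    expect_true(ann2$transcripts$coding)   # coding via CDS record

    g3 <- gtfGene("chr1", "gC", "+", list(c(1, 100)), biotype = "lncRNA")
    expect_false(readAnnotation(writeGtf(g3))$transcripts$coding)

    # exon referencing an unknown transcript
    bad <- c(gtfGene("chr1", "gD", "+", list(c(1, 100))),
             paste("chr1", "t", "exon", 1, 50, ".", "+", ".",
                   'gene_id "gD"; transcript_id "ghost";', sep = "\t"))
    expect_error(readAnnotation(writeGtf(bad)), "unknown transcript")

    # exon outside the declared gene span
    bad2 <- gtfGene("chr1", "gE", "+", list(c(1, 100), c(900, 950)),
                    span = c(1, 500))
    expect_error(readAnnotation(writeGtf(bad2)), "outside the span")
})

test_that("flattening produces maximal constant-coverage bins", {
    # two overlapping exons of two transcripts of one gene
    g <- c(gtfGene("chr1", "g1", "+", list(c(1, 100)), tx = "t1",
                   span = c(1, 150)),
           gtfGene("chr1", "g1", "+", list(c(51, 150)), tx = "t2",
                   span = c(1, 150)))
    ann <- readAnnotation(writeGtf(g))
    bins <- flattenExons(ann)
    expect_equal(start(bins), c(1L, 51L, 101L))
    expect_equal(end(bins), c(50L, 100L, 150L))
    expect_equal(as.list(mcols(bins)$transcripts),
                 list("t1", c("t1", "t2"), "t2"))

    # non-overlapping exons flatten to themselves
    g2 <- gtfGene("chr1", "g2", "+", list(c(1, 100), c(201, 300)))
    b2 <- flattenExons(readAnnotation(writeGtf(g2)))
    expect_equal(start(b2), c(1L, 201L))
    expect_equal(end(b2), c(100L, 300L))
})

test_that("a bin shared by two genes is duplicated per gene, unless genewise", {
    g <- c(gtfGene("chr1", "gA", "+", list(c(1, 100)), tx = "tA"),
           gtfGene("chr1", "gB", "+", list(c(51, 150)), tx = "tB"))
    ann <- readAnnotation(writeGtf(g))
    bins <- flattenExons(ann, genewise = FALSE)
    shared <- bins[start(bins) == 51 & end(bins) == 100]
    expect_equal(length(shared), 2L)
    expect_setequal(mcols(shared)$gene, c("gA", "gB"))
    expect_true(all(mcols(shared)$geneAmbiguous))
    expect_equal(as.list(mcols(shared)$transcripts),
                 list("tA", "tB"))   # each copy keeps its gene's transcripts

    gw <- flattenExons(ann, genewise = TRUE)
    expect_equal(sort(start(gw[mcols(gw)$gene == "gA"])), 1L)
    expect_equal(end(gw[mcols(gw)$gene == "gA"]), 100L)  # not fragmented
    expect_false(any(mcols(gw)$geneAmbiguous))
})

test_that("bins are labeled CDS / UTR / 3UTR / non-coding correctly", {
    toy <- makeToyAnnotation()
    bins <- prepareBins(toy$gtf)   # no APA
    df <- binFrame(bins)
    pick <- function(s, e) df$type[df$start == s & df$end == e]
    expect_equal(pick(101, 200), "CDS")       # overlaps CDS interval
    expect_equal(pick(301, 400), "CDS")
    # downstream of last CDS of coding tx1
    expect_equal(pick(501, 600), "3UTR")
    # only biotype-coding tx2 (no CDS records): conservative UTR label
    expect_equal(pick(401, 450), "UTR")
    expect_equal(pick(8001, 8500), "non-coding")
    # minus strand: 3' UTR at the low-coordinate end
    expect_equal(pick(5201, 5400), "3UTR")
})

test_that("APA segmentation: boundary-to-site bins at 300 and 500", {
    g <- gtfGene("chr1", "g1", "+", list(c(1, 200)), list(c(21, 120)))
    ann <- readAnnotation(writeGtf(g))
    bins <- labelBins(flattenExons(ann), ann)
    apa <- rtracklayer::import(writeBed("chr1", c(300, 500), "+"))
    out <- applyApaSites(bins, apa, genes = ann$genes)
    new <- binFrame(out[mcols(out)$apaDerived])
    expect_equal(new$start, c(201, 301))
    expect_equal(new$end, c(300, 500))
    expect_equal(new$type, c("3UTR", "3UTR"))
    expect_equal(new$gene, c("g1", "g1"))
})

test_that("over-long UTRs, gene-start-guarded sites and edge sites are dropped", {
    toy <- makeToyAnnotation()
    bins <- prepareBins(toy$gtf, apa = toy$bed)
    df <- binFrame(bins)
    # maxUTRbinSize: chr2 site 20 kb downstream produced nothing
    expect_equal(nrow(df[df$chrom == "chr2", ]), 1L)
    expect_false(any(df$apaDerived[df$chrom == "chr2"]))
    # gene-start guard: chr3 site between gene5 and gene6 produced nothing
    expect_equal(nrow(df[df$chrom == "chr3", ]), 2L)
    expect_false(any(df$apaDerived[df$chrom == "chr3"]))
    # raising the limit rescues the far site
    wide <- prepareBins(toy$gtf, apa = toy$bed, maxUTRbinSize = 25000)
    expect_true(any(binFrame(wide)$apaDerived[
        as.character(seqnames(wide)) == "chr2"]))

    # a site coinciding with an existing 3' edge is a no-op
    g <- gtfGene("chr1", "g1", "+", list(c(1, 200)), list(c(21, 120)))
    ann <- readAnnotation(writeGtf(g))
    b0 <- labelBins(flattenExons(ann), ann)
    edge <- rtracklayer::import(writeBed("chr1", 200, "+"))
    expect_equal(binFrame(applyApaSites(b0, edge, genes = ann$genes)),
                 binFrame(b0))
})

test_that("APA input validation: strands and chromosomes", {
    g <- gtfGene("chr1", "g1", "+", list(c(1, 200)), list(c(21, 120)))
    ann <- readAnnotation(writeGtf(g))
    bins <- labelBins(flattenExons(ann), ann)
    unstr <- GRanges("chr1", IRanges(300, 300), strand = "*")
    expect_error(applyApaSites(bins, unstr), "unstranded")
    offchr <- GRanges("chrZ", IRanges(300, 300), strand = "+")
    expect_warning(out <- applyApaSites(bins, offchr, genes = ann$genes),
                   "skipped")
    expect_equal(length(out), length(bins))
})

test_that("bins are disjoint within genes, cover the exons, and rebuild identically", {
    toy <- makeToyAnnotation()
    ann <- readAnnotation(toy$gtf)
    bins <- prepareBins(ann, apa = toy$bed)
    # disjointness per gene
    for (g in unique(mcols(bins)$gene)) {
        b <- bins[mcols(bins)$gene == g]
        expect_equal(sum(width(GenomicRanges::reduce(b))), sum(width(b)))
    }
    # coverage: the bins cover the exon union bp-exactly, and any bin
    # territory outside the exons comes from APA extensions only
    all <- GenomicRanges::reduce(granges(bins), ignore.strand = FALSE)
    exu <- GenomicRanges::reduce(granges(ann$exons), ignore.strand = FALSE)
    expect_equal(sum(width(GenomicRanges::intersect(all, exu))),
                 sum(width(exu)))
    extra <- GenomicRanges::setdiff(all, exu)
    apaCov <- GenomicRanges::reduce(granges(bins[mcols(bins)$apaDerived]))
    expect_equal(sum(width(GenomicRanges::intersect(extra, apaCov))),
                 sum(width(extra)))
    # determinism: identical inputs give identical serializations
    again <- prepareBins(readAnnotation(toy$gtf), apa = toy$bed)
    expect_identical(binFrame(bins), binFrame(again))
})

test_that("mirrored annotations give mirrored bins with identical labels", {
    L <- 10000L
    mk <- function(strand, flip) {
        tr <- function(iv) if (flip) c(L - iv[2] + 1L, L - iv[1] + 1L) else iv
        g <- gtfGene("chr1", "g1", strand,
                     lapply(list(c(101, 300), c(501, 700)), tr),
                     lapply(list(c(151, 300), c(501, 550)), tr))
        ann <- readAnnotation(writeGtf(g))
        pos <- if (flip) L - c(900L, 1100L) + 1L else c(900L, 1100L)
        apa <- rtracklayer::import(writeBed("chr1", pos, strand))
        applyApaSites(labelBins(flattenExons(ann), ann), apa,
                      genes = ann$genes)
    }
    fwd <- binFrame(mk("+", FALSE))
    rev <- binFrame(mk("-", TRUE))
    rev$start2 <- L - rev$end + 1L
    rev$end2 <- L - rev$start + 1L
    rev <- rev[order(rev$start2), ]
    fwd <- fwd[order(fwd$start), ]
    expect_equal(fwd$start, rev$start2)
    expect_equal(fwd$end, rev$end2)
    expect_equal(fwd$type, rev$type)
    expect_equal(fwd$apaDerived, rev$apaDerived)
})
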