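#' @importFrom GenomicRanges disjoin findOverlaps reduce
#' @importFrom IRanges CharacterList resize
#' @importFrom S4Vectors queryHits subjectHits
NULL

# canonical bin ordering: (chrom, start, end, gene)
sortBins <- function(bins) {
    o <- order(as.character(seqnames(bins)), start(bins), end(bins),
               mcols(bins)$gene)
    bins <- bins[o]
    names(bins) <- binIds(bins)
    bins
}

#' Flatten exons into disjoint counting bins
#'
#' Fragments the exon annotation into the widest intervals over which the set
#' of overlapping exon features is constant. Each bin carries the ids of the
#' transcripts whose exons cover it. With \code{genewise = FALSE} (default)
#' flattening is done across genes: a bin covered by exons of two or more
#' genes is emitted once per gene with \code{geneAmbiguous = TRUE}, so each
#' gene contains the shared fragment once. With \code{genewise = TRUE} each
#' gene is flattened independently and no ambiguity flag is set.
#'
#' @param ann an \code{AnnotationModel} from \code{\link{readAnnotation}}.
#' @param genewise logical; flatten each gene separately.
#' @return A \code{GRanges} of bins with metadata columns \code{gene},
#'   \code{transcripts} (CharacterList), \code{geneAmbiguous},
#'   \code{apaDerived} (all \code{FALSE} at this stage) and \code{type}
#'   (\code{NA} until \code{\link{labelBins}}).
#' @export
flattenExons <- function(ann, genewise = FALSE) {
    ex <- ann$exons
    pieces <- if (genewise) {
        grl <- split(ex, mcols(ex)$gene_id)
        res <- lapply(names(grl), function(g) {
            e <- grl[[g]]
            d <- disjoin(e, with.revmap = TRUE)
            rv <- mcols(d)$revmap
            mcols(d) <- NULL
            mcols(d)$gene <- g
            mcols(d)$transcripts <- CharacterList(lapply(rv, function(i)
                unique(mcols(e)$tx_id[i])))
            mcols(d)$geneAmbiguous <- FALSE
            d
        })
        suppressWarnings(do.call(c, res))
    } else {
        d <- disjoin(ex, with.revmap = TRUE)
        rv <- mcols(d)$revmap
        txs <- mcols(ex)$tx_id
        gns <- mcols(ex)$gene_id
        geneSets <- lapply(rv, function(i) unique(gns[i]))
        n <- lengths(geneSets)
        out <- rep(d, n)
        mcols(out) <- NULL
        mcols(out)$gene <- unlist(geneSets)
        # per duplicate, keep only the assigned gene's transcripts
        rvRep <- rep(rv, n)
        mcols(out)$transcripts <- CharacterList(mapply(function(i, g)
            unique(txs[i][gns[i] == g]), rvRep, mcols(out)$gene,
            SIMPLIFY = FALSE))
        mcols(out)$geneAmbiguous <- rep(n > 1L, n)
        out
    }
    mcols(pieces)$apaDerived <- FALSE
    mcols(pieces)$type <- NA_character_
    sortBins(pieces)
}

#' Label bins as CDS, UTR, 3' UTR or non-coding
#'
#' A bin overlapping any annotated CDS interval is labeled \code{CDS}. A bin
#' with no CDS overlap whose transcript set includes a protein-coding
#' transcript is labeled \code{UTR}; if it additionally lies strand-aware
#' downstream of the last CDS of one of its coding transcripts it is
#' relabeled \code{3UTR}. Bins with no protein-coding transcript are labeled
#' \code{non-coding}. Coding transcripts without CDS records (coding by
#' biotype only) provide no stop-codon boundary, so their UTR bins keep the
#' conservative \code{UTR} label.
#'
#' @param bins bins from \code{\link{flattenExons}}.
#' @param ann the \code{AnnotationModel} the bins were built from.
#' @return The bins with the \code{type} column filled.
#' @export
labelBins <- function(bins, ann) {
    codingTx <- ann$transcripts$tx_id[ann$transcripts$coding]
    overCds <- rep(FALSE, length(bins))
    if (length(ann$cds))
        overCds[unique(queryHits(findOverlaps(bins, ann$cds)))] <- TRUE
    hasCoding <- vapply(mcols(bins)$transcripts,
                        function(tx) any(tx %in% codingTx), logical(1))
    type <- ifelse(overCds, "CDS", ifelse(hasCoding, "UTR", "non-coding"))

    # strand-aware last-CDS boundary per transcript with CDS records
    if (length(ann$cds)) {
        cdsTx <- mcols(ann$cds)$tx_id
        lastEnd <- tapply(end(ann$cds), cdsTx, max)      # + strand boundary
        firstStart <- tapply(start(ann$cds), cdsTx, min) # - strand boundary
        isUtr <- which(type == "UTR")
        if (length(isUtr)) {
            plus <- as.character(strand(bins)) == "+"
            down <- vapply(isUtr, function(i) {
                txs <- intersect(mcols(bins)$transcripts[[i]], names(lastEnd))
                if (!length(txs)) return(FALSE)
                if (plus[i]) any(start(bins)[i] > lastEnd[txs])
                else any(end(bins)[i] < firstStart[txs])
            }, logical(1))
            type[isUtr[down]] <- "3UTR"
        }
    }
    mcols(bins)$type <- type
    bins
}

#' Segment and extend 3' UTR bins at poly(A) sites
#'
#' For every stranded poly(A) site, the closest strand-aware upstream CDS or
#' UTR bin boundary is located and a new 3' UTR bin is defined from that
#' boundary (exclusive) to the site (inclusive), assigned to the boundary
#' bin's gene and transcripts, with \code{apaDerived = TRUE}. A site falling
#' inside an existing UTR/3' UTR bin splits that bin at the site; sites inside
#' CDS bins are ignored (new UTRs are only defined from CDS/UTR context).
#' A candidate UTR longer than \code{maxUTRbinSize} is discarded as unlikely
#' to be a real UTR, and so is a candidate whose nearest upstream feature is
#' the start of a(nother) gene rather than a CDS/UTR bin, to avoid assignment
#' problems. Sites are processed in transcription order, so consecutive
#' downstream sites produce consecutive segments.
#'
#' @param bins labeled bins from \code{\link{labelBins}}.
#' @param apa a \code{GRanges} of single-base poly(A) sites
#'   (\code{\link{readApaSites}}).
#' @param maxUTRbinSize maximum width (bp) of a newly defined UTR bin.
#' @param genes optional \code{GRanges} of gene spans (named by gene id) used
#'   for the gene-start guard; defaults to the span of each gene's bins.
#' @return The augmented, re-sorted bins.
#' @export
applyApaSites <- function(bins, apa, maxUTRbinSize = 15000, genes = NULL) {
    if (length(apa) == 0L) return(bins)
    if (any(as.character(strand(apa)) == "*"))
        stop("unstranded APA sites are not supported (upstream/downstream undefined)")
    if (any(as.character(strand(bins)) == "*"))
        stop("unstranded annotations are not supported for APA processing")
    binChroms <- unique(as.character(seqnames(bins)))
    off <- !(as.character(seqnames(apa)) %in% binChroms)
    if (any(off)) {
        warning(sum(off), " APA site(s) on chromosomes absent from the ",
                "annotation were skipped")
        apa <- apa[!off]
    }
    if (is.null(genes)) {
        sp <- split(granges(bins), mcols(bins)$gene)
        genes <- unlist(range(sp))
    }

    b <- data.frame(chrom = as.character(seqnames(bins)),
                    start = start(bins), end = end(bins),
                    strand = as.character(strand(bins)),
                    gene = mcols(bins)$gene, type = mcols(bins)$type,
                    geneAmbiguous = mcols(bins)$geneAmbiguous,
                    apaDerived = mcols(bins)$apaDerived,
                    stringsAsFactors = FALSE)
    b$transcripts <- as.list(mcols(bins)$transcripts)
    g <- data.frame(chrom = as.character(seqnames(genes)),
                    start = start(genes), end = end(genes),
                    strand = as.character(strand(genes)),
                    stringsAsFactors = FALSE)

    pos <- start(apa)
    ord <- order(as.character(seqnames(apa)),
                 ifelse(as.character(strand(apa)) == "+", pos, -pos))
    apa <- apa[ord]

    for (j in seq_along(apa)) {
        p <- start(apa)[j]
        chr <- as.character(seqnames(apa))[j]
        st <- as.character(strand(apa))[j]
        el <- which(b$chrom == chr & b$strand == st &
                        b$type %in% c("CDS", "UTR", "3UTR"))
        if (!length(el)) next
        inside <- el[b$start[el] <= p & b$end[el] >= p]
        if (length(inside)) {
            for (i in sort(inside, decreasing = TRUE)) {
                if (b$type[i] == "CDS") next
                # split at the site; a site at the 3' edge is a no-op
                if (st == "+") {
                    if (p == b$end[i]) next
                    prox <- b[i, ]; prox$end <- p
                    dist <- b[i, ]; dist$start <- p + 1L
                } else {
                    if (p == b$start[i]) next
                    prox <- b[i, ]; prox$start <- p
                    dist <- b[i, ]; dist$end <- p - 1L
                }
                prox$apaDerived <- TRUE; dist$apaDerived <- TRUE
                b <- rbind(b[-i, ], prox, dist)
            }
            next
        }
        # extension: nearest strand-aware upstream 3' edge of an eligible bin
        if (st == "+") {
            up <- el[b$end[el] < p]
            if (!length(up)) next
            edge <- max(b$end[up])
            gs <- g$start[g$chrom == chr & g$strand == st & g$start <= p]
            if (length(gs) && max(gs) > edge) next        # gene-start guard
            newWidth <- p - edge
            if (newWidth > maxUTRbinSize) next
            anchors <- up[b$end[up] == edge]
            for (i in anchors) {
                nb <- b[i, ]
                nb$start <- edge + 1L; nb$end <- p
                nb$type <- "3UTR"; nb$apaDerived <- TRUE
                b <- rbind(b, nb)
            }
        } else {
            up <- el[b$start[el] > p]
            if (!length(up)) next
            edge <- min(b$start[up])
            ge <- g$end[g$chrom == chr & g$strand == st & g$end >= p]
            if (length(ge) && min(ge) < edge) next        # gene-start guard
            newWidth <- edge - p
            if (newWidth > maxUTRbinSize) next
            anchors <- up[b$start[up] == edge]
            for (i in anchors) {
                nb <- b[i, ]
                nb$start <- p; nb$end <- edge - 1L
                nb$type <- "3UTR"; nb$apaDerived <- TRUE
                b <- rbind(b, nb)
            }
        }
    }
    out <- GRanges(b$chrom, IRanges(b$start, b$end), strand = b$strand)
    mcols(out)$gene <- b$gene
    mcols(out)$transcripts <- CharacterList(b$transcripts)
    mcols(out)$geneAmbiguous <- b$geneAmbiguous
    mcols(out)$apaDerived <- b$apaDerived
    mcols(out)$type <- b$type
    out <- sortBins(out)
    stopifnot(!binsOverlapWithinGene(out))
    out
}

# TRUE if any two bins of the same gene share a base
binsOverlapWithinGene <- function(bins) {
    sp <- split(granges(bins), mcols(bins)$gene)
    any(vapply(sp, function(x)
        sum(width(reduce(x, ignore.strand = TRUE))) != sum(width(x)),
        logical(1)))
}

#' Build labeled counting bins from an annotation and poly(A) sites
#'
#' One-stop wrapper: \code{\link{readAnnotation}} (if given paths),
#' \code{\link{flattenExons}}, \code{\link{labelBins}} and, when APA sites
#' are supplied, \code{\link{applyApaSites}}.
#'
#' @param annotation an \code{AnnotationModel} or path to a GTF/GFF3 file.
#' @param apa optional \code{GRanges} of poly(A) sites or path to a BED file.
#' @param maxUTRbinSize maximum width of an APA-derived UTR bin (bp).
#' @param genewise flatten each gene independently.
#' @return A sorted, labeled \code{GRanges} of bins;
#'   \code{metadata()} records the build parameters.
#' @export
prepareBins <- function(annotation, apa = NULL, maxUTRbinSize = 15000,
                        genewise = FALSE) {
    ann <- if (inherits(annotation, "AnnotationModel")) annotation
           else readAnnotation(annotation)
    bins <- labelBins(flattenExons(ann, genewise = genewise), ann)
    if (!is.null(apa)) {
        if (is.character(apa)) apa <- readApaSites(apa)
        bins <- applyApaSites(bins, apa, maxUTRbinSize = maxUTRbinSize,
                              genes = ann$genes)
    }
    metadata(bins) <- list(maxUTRbinSize = maxUTRbinSize, genewise = genewise)
    bins
}

#' Write bins as a BED-like TSV
#'
#' Columns: chrom, start (0-based), end, name (\code{gene:binIndex}), score
#' (bin width in bp), strand, type, geneAmbiguous, apaDerived. A commented
#' header states the coordinate convention.
#'
#' @param bins a bin \code{GRanges}.
#' @param path output file.
#' @export
writeBinsBed <- function(bins, path) {
    df <- data.frame(chrom = as.character(seqnames(bins)),
                     start = start(bins) - 1L, end = end(bins),
                     name = names(bins), score = width(bins),
                     strand = as.character(strand(bins)),
                     type = mcols(bins)$type,
                     geneAmbiguous = mcols(bins)$geneAmbiguous,
                     apaDerived = mcols(bins)$apaDerived)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# binsplice bins v1 (BED convention: 0-based half-open)",
                 paste0("# ", paste(colnames(df), collapse = "\t"))), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
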