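#' @importFrom rtracklayer import
#' @importFrom GenomicRanges GRanges GRangesList
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqnames seqlevels seqlevelsInUse keepSeqlevels
#' @importFrom BiocGenerics strand start end width unlist
NULL

#' Read a gene annotation (GTF/GFF3)
#'
#' Imports a GTF or GFF3 annotation (gzip allowed) and assembles a validated
#' gene model: gene spans, transcripts with their exon and CDS intervals, and
#' coding status. A transcript is considered protein-coding if it has at
#' least one CDS record or carries the biotype \code{"protein_coding"}
#' (GTF dialects differ in which of the two they provide). Transcripts
#' lacking CDS records and a coding biotype are treated as non-coding.
#' Coordinates are kept in the native GTF convention (1-based, inclusive).
#'
#' @param path path to a GTF or GFF3 file.
#' @return An object of class \code{AnnotationModel}: a list with elements
#'   \code{genes} (GRanges named by gene id), \code{transcripts} (DataFrame
#'   with \code{tx_id}, \code{gene_id}, \code{biotype}, \code{coding}),
#'   \code{exons} and \code{cds} (GRanges with \code{tx_id}, \code{gene_id}).
#' @export
readAnnotation <- function(path) {
    if (!file.exists(path)) stop("annotation file not found: ", path)
    fmt <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
        "gff3" else "gtf"
    gr <- tryCatch(rtracklayer::import(path, format = fmt),
                   error = function(e) stop("failed to parse ", path, ": ",
                                            conditionMessage(e), call. = FALSE))
    mc <- mcols(gr)
    typ <- as.character(mc$type)
    getAttr <- function(obj, keys) {
        for (k in keys) if (k %in% colnames(mcols(obj)))
            return(as.character(mcols(obj)[[k]]))
        rep(NA_character_, length(obj))
    }
    ex <- gr[typ == "exon"]
    cds <- gr[typ == "CDS"]
    if (length(ex) == 0L) stop("no exon features in ", path)
    exTx <- getAttr(ex, c("transcript_id", "Parent"))
    exGene <- getAttr(ex, c("gene_id"))
    if (anyNA(exTx)) {
        bad <- which(is.na(exTx))[1]
        stop("exon record ", bad, " lacks a transcript_id attribute")
    }
    cdsTx <- getAttr(cds, c("transcript_id", "Parent"))
    cdsGene <- getAttr(cds, c("gene_id"))

    txRec <- gr[typ %in% c("transcript", "mRNA")]
    txTbl <- DataFrame(tx_id = getAttr(txRec, c("transcript_id", "ID")),
                       gene_id = getAttr(txRec, c("gene_id")),
                       biotype = getAttr(txRec, c("transcript_biotype",
                                                  "transcript_type")))
    if (length(txRec)) {
        unknown <- setdiff(exTx, txTbl$tx_id)
        if (length(unknown))
            stop("exon(s) reference unknown transcript(s): ",
                 paste(head(unknown, 3), collapse = ", "))
    } else {
        txTbl <- DataFrame(tx_id = unique(exTx))
        txTbl$gene_id <- exGene[match(txTbl$tx_id, exTx)]
        txTbl$biotype <- NA_character_
    }
    # exon gene ids may be absent in GFF3; fill from the transcript table
    if (anyNA(exGene)) exGene <- txTbl$gene_id[match(exTx, txTbl$tx_id)]
    if (anyNA(cdsGene) && length(cds))
        cdsGene <- txTbl$gene_id[match(cdsTx, txTbl$tx_id)]
    mcols(ex) <- DataFrame(tx_id = exTx, gene_id = exGene)
    mcols(cds) <- DataFrame(tx_id = cdsTx, gene_id = cdsGene)

    geneRec <- gr[typ == "gene"]
    if (length(geneRec)) {
        genes <- granges(geneRec)
        names(genes) <- getAttr(geneRec, c("gene_id", "ID"))
        mcols(genes)$biotype <- getAttr(geneRec, c("gene_biotype", "gene_type"))
    } else {
        sp <- split(granges(ex), exGene)
        genes <- unlist(range(sp))
        mcols(genes)$biotype <- NA_character_
    }
    # every exon must fall inside its gene's span
    gi <- match(exGene, names(genes))
    if (anyNA(gi))
        stop("exon(s) reference unknown gene(s): ",
             paste(head(unique(exGene[is.na(gi)]), 3), collapse = ", "))
    inside <- as.character(seqnames(ex)) == as.character(seqnames(genes))[gi] &
        start(ex) >= start(genes)[gi] & end(ex) <= end(genes)[gi]
    if (any(!inside))
        stop("exon record(s) outside the span of their gene: ",
             paste(head(which(!inside), 3), collapse = ", "))

    txTbl$coding <- txTbl$tx_id %in% cdsTx |
        (!is.na(txTbl$biotype) & txTbl$biotype == "protein_coding")
    ann <- list(genes = genes, transcripts = txTbl, exons = ex, cds = cds)
    class(ann) <- "AnnotationModel"
    ann
}

#' @export
print.AnnotationModel <- function(x, ...) {
    cat(sprintf("AnnotationModel: %d genes, %d transcripts (%d coding), %d exons, %d CDS\n",
                length(x$genes), nrow(x$transcripts), sum(x$transcripts$coding),
                length(x$exons), length(x$cds)))
    invisible(x)
}

#' Read alternative-polyadenylation sites from a BED file
#'
#' Poly(A) sites are expected as single-base BED records (0-based half-open on
#' disk; converted to 1-based positions on read, as done by
#' \code{rtracklayer}). Records wider than one base are collapsed to their
#' strand-aware 3' end with a warning. Sites must be stranded to be usable:
#' upstream/downstream is undefined otherwise.
#'
#' @param path path to a BED3/BED6 file.
#' @return A \code{GRanges} of single-base sites.
#' @export
readApaSites <- function(path) {
    if (!file.exists(path)) stop("APA site file not found: ", path)
    sites <- rtracklayer::import(path, format = "bed")
    if (any(width(sites) != 1L)) {
        warning("APA records wider than 1 bp collapsed to their 3' end")
        sites <- resize(sites, width = 1L, fix = "end")
    }
    sites
}
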