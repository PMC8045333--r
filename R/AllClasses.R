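#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<- Rle
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges
#'   rowData rowData<- colData colData<-
#' @importFrom GenomicRanges GRanges granges
NULL

#' Bin-level count container
#'
#' \code{BinnedCounts} extends \code{RangedSummarizedExperiment}: rows are
#' disjoint counting bins (a \code{GRanges} carrying \code{gene}, \code{type},
#' \code{geneAmbiguous} and \code{apaDerived} metadata columns), columns are
#' samples, and the \code{"counts"} assay holds non-negative integer read
#' counts. \code{colData} records the per-sample library size (the number of
#' usable alignments), a TMM normalization factor (1 until
#' \code{\link{tmmNormFactors}} is run) and, optionally, a \code{condition}
#' label. Differential-usage results are written back into \code{rowData} and
#' \code{metadata} by \code{\link{diffSpliceBins}}.
#'
#' @slot .. see \code{RangedSummarizedExperiment}; no additional slots.
#' @aliases BinnedCounts-class
#' @exportClass BinnedCounts
setClass("BinnedCounts", contains = "RangedSummarizedExperiment")

setValidity("BinnedCounts", function(object) {
    msg <- NULL
    if (!"counts" %in% names(assays(object)))
        msg <- c(msg, "a 'counts' assay is required")
    else {
        cnt <- assay(object, "counts")
        if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
        if (any(abs(cnt - round(cnt)) > 1e-8))
            msg <- c(msg, "counts must be integers")
    }
    if (!"libSize" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain 'libSize'")
    else if (ncol(object) > 0L) {
        ls <- colData(object)$libSize
        nonEmpty <- colSums(assay(object, "counts")) > 0
        if (any(ls[nonEmpty] <= 0))
            msg <- c(msg, "library sizes must be > 0 for non-empty samples")
    }
    if (!"normFactor" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain 'normFactor'")
    needed <- c("gene", "type")
    miss <- setdiff(needed, colnames(rowData(object)))
    if (length(miss))
        msg <- c(msg, paste0("rowData must contain: ",
                             paste(miss, collapse = ", ")))
    if (is.null(msg)) TRUE else msg
})

#' Construct a BinnedCounts object
#'
#' @param counts integer matrix of bin counts (bins x samples).
#' @param bins \code{GRanges} of bins, as produced by \code{\link{prepareBins}}
#'   (metadata columns \code{gene}, \code{type}, and optionally
#'   \code{geneAmbiguous}, \code{apaDerived}, \code{transcripts}).
#' @param libSize per-sample library sizes; defaults to column sums.
#' @param normFactor per-sample normalization factors; defaults to 1.
#' @param condition optional per-sample condition labels.
#' @return A \code{\link{BinnedCounts}} object.
#' @export
BinnedCounts <- function(counts, bins, libSize = NULL, normFactor = NULL,
                         condition = NULL) {
    counts <- as.matrix(counts)
    mode(counts) <- "numeric"
    if (nrow(counts) != length(bins))
        stop("nrow(counts) must equal length(bins)")
    if (is.null(libSize)) libSize <- colSums(counts)
    if (is.null(normFactor)) normFactor <- rep(1, ncol(counts))
    cd <- DataFrame(libSize = as.numeric(libSize),
                    normFactor = as.numeric(normFactor),
                    row.names = colnames(counts))
    if (!is.null(condition)) cd$condition <- condition
    if (!"geneAmbiguous" %in% colnames(mcols(bins)))
        mcols(bins)$geneAmbiguous <- FALSE
    if (!"apaDerived" %in% colnames(mcols(bins)))
        mcols(bins)$apaDerived <- FALSE
    if (is.null(names(bins)))
        names(bins) <- binIds(bins)
    rownames(counts) <- names(bins)
    se <- SummarizedExperiment(assays = list(counts = counts),
                               rowRanges = bins, colData = cd)
    new("BinnedCounts", se)
}

#' Accessors for BinnedCounts
#'
#' \code{binCounts} returns the count matrix, \code{libSizes} the per-sample
#' library sizes, \code{normFactors} the TMM normalization factors,
#' \code{conditions} the condition labels (or \code{NULL}), \code{binTypes}
#' the bin type labels and \code{geneIds} the per-bin gene assignment.
#'
#' @param object a \code{BinnedCounts}.
#' @param value replacement value.
#' @name BinnedCounts-accessors
#' @export
binCounts <- function(object) assay(object, "counts")

#' @rdname BinnedCounts-accessors
#' @export
libSizes <- function(object) setNames(colData(object)$libSize, colnames(object))

#' @rdname BinnedCounts-accessors
#' @export
normFactors <- function(object)
    setNames(colData(object)$normFactor, colnames(object))

#' @rdname BinnedCounts-accessors
#' @export
`normFactors<-` <- function(object, value) {
    colData(object)$normFactor <- as.numeric(value)
    validObject(object)
    object
}

#' @rdname BinnedCounts-accessors
#' @export
conditions <- function(object) colData(object)$condition

#' @rdname BinnedCounts-accessors
#' @export
binTypes <- function(object) rowData(object)$type

#' @rdname BinnedCounts-accessors
#' @export
geneIds <- function(object) rowData(object)$gene

setMethod("show", "BinnedCounts", function(object) {
    cat("class: BinnedCounts\n")
    cat(sprintf("bins: %d  samples: %d\n", nrow(object), ncol(object)))
    tt <- table(binTypes(object))
    cat("bin types:", paste(names(tt), tt, sep = "=", collapse = " "), "\n")
    cat(sprintf("genes: %d\n", length(unique(geneIds(object)))))
    if (!is.null(conditions(object)))
        cat("conditions:", paste(unique(as.character(conditions(object))),
                                 collapse = ", "), "\n")
    if (!is.null(metadata(object)$method))
        cat("differential analysis:", metadata(object)$method, "\n")
    invisible(NULL)
})

# Stable "gene:index" bin identifiers for a sorted bin GRanges.
binIds <- function(bins) {
    gene <- mcols(bins)$gene
    idx <- stats::ave(seq_along(bins), gene, FUN = seq_along)
    paste0(gene, ":", idx)
}
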