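#' @importFrom Rsamtools ScanBamParam scanBamFlag asBam BamFile scanBamHeader
#'   testPairedEndBam
#' @importFrom GenomicAlignments readGAlignments readGAlignmentPairs grglist
#' @importFrom GenomicRanges countOverlaps
NULL

# Accept SAM transparently: convert to a coordinate-sorted, indexed BAM.
ensureBam <- function(path) {
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
        dest <- tempfile(fileext = "")
        asBam(path, destination = dest, overwrite = TRUE, indexDestination = TRUE)
    } else path
}

#' Count aligned reads per bin
#'
#' Assigns every usable alignment once to every bin it overlaps by at least
#' one base, so a read spanning several bins is counted several times (many
#' bins are shorter than the read length). Overlap is evaluated against the
#' aligned blocks of the CIGAR string, so an intron-spanning read does not
#' count bins inside its gap. For paired-end data a fragment is counted once
#' per bin that either mate overlaps. Unmapped, secondary and supplementary
#' alignments are excluded; the library size of a sample is its number of
#' usable alignments (fragments), whether or not they hit a bin.
#'
#' @param bins a bin \code{GRanges} from \code{\link{prepareBins}}.
#' @param files character vector of BAM (or SAM) paths, one per sample.
#' @param sampleNames sample ids; defaults to file base names.
#' @param stranded \code{"none"} (default), \code{"forward"} (read strand
#'   must match the bin) or \code{"reverse"} (opposite strand protocol).
#' @param condition optional per-sample condition labels.
#' @param mapqFilter minimum mapping quality (default 0 = keep all).
#' @param dropDuplicates drop alignments with the PCR-duplicate flag
#'   (default \code{FALSE}).
#' @return A \code{\link{BinnedCounts}} object.
#' @export
countBinReads <- function(bins, files, sampleNames = NULL,
                          stranded = c("none", "forward", "reverse"),
                          condition = NULL, mapqFilter = 0,
                          dropDuplicates = FALSE) {
    stranded <- match.arg(stranded)
    if (is.null(sampleNames))
        sampleNames <- tools::file_path_sans_ext(basename(files))
    flag <- scanBamFlag(isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
                        isSupplementaryAlignment = FALSE,
                        isDuplicate = if (dropDuplicates) FALSE else NA)
    param <- ScanBamParam(flag = flag, mapqFilter = mapqFilter)
    counts <- matrix(0L, nrow = length(bins), ncol = length(files))
    libSize <- numeric(length(files))
    for (s in seq_along(files)) {
        bam <- ensureBam(files[s])
        hdr <- scanBamHeader(bam)[[1]]$targets
        if (!any(unique(as.character(seqnames(bins))) %in% names(hdr)))
            stop("no bin chromosome matches the alignment header of ",
                 files[s], "; check naming (e.g. 'chr1' vs '1') and supply ",
                 "a renamed annotation")
        paired <- suppressMessages(testPairedEndBam(bam))
        blocks <- if (paired)
            grglist(readGAlignmentPairs(bam, param = param))
        else grglist(readGAlignments(bam, param = param))
        libSize[s] <- length(blocks)
        if (stranded == "reverse")
            blocks <- invertStrand(blocks)
        counts[, s] <- countOverlaps(bins, blocks,
                                     ignore.strand = (stranded == "none"))
    }
    colnames(counts) <- sampleNames
    BinnedCounts(counts, bins, libSize = libSize, condition = condition)
}

#' Write / read a bin count matrix as TSV
#'
#' The TSV has columns \code{bin}, \code{gene}, \code{type} followed by one
#' integer column per sample; a commented header records library sizes and
#' normalization factors so that a round trip is lossless.
#'
#' @param object a \code{BinnedCounts}.
#' @param path file path.
#' @export
writeCountMatrix <- function(object, path) {
    df <- data.frame(bin = rownames(object), gene = geneIds(object),
                     type = binTypes(object), binCounts(object),
                     check.names = FALSE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# binsplice counts v1",
                 paste0("# libSize: ", paste(colnames(object), libSizes(object),
                                             sep = "=", collapse = "\t")),
                 paste0("# normFactor: ",
                        paste(colnames(object), normFactors(object),
                              sep = "=", collapse = "\t"))), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeCountMatrix
#' @param bins the bin \code{GRanges} the counts refer to; every bin id in the
#'   file must be present.
#' @param samples optional character vector of required sample ids; an absent
#'   column is an error naming the sample.
#' @export
readCountMatrix <- function(path, bins, samples = NULL) {
    if (!file.exists(path)) stop("count matrix not found: ", path)
    hdr <- readLines(path, n = 20)
    hdr <- hdr[startsWith(hdr, "#")]
    df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                            stringsAsFactors = FALSE)
    idCols <- intersect(c("bin", "gene", "type"), colnames(df))
    sampleCols <- setdiff(colnames(df), idCols)
    if (!is.null(samples)) {
        miss <- setdiff(samples, sampleCols)
        if (length(miss))
            stop("sample column(s) missing from count matrix: ",
                 paste(miss, collapse = ", "))
        sampleCols <- samples
    }
    cnt <- as.matrix(df[, sampleCols, drop = FALSE])
    if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
        stop("counts must be non-negative integers")
    bad <- setdiff(df$bin, names(bins))
    if (length(bad))
        stop("bin id(s) absent from the provided bins: ",
             paste(head(bad, 3), collapse = ", "))
    bins <- bins[df$bin]
    parseKv <- function(tag) {
        ln <- grep(paste0("^# ", tag, ":"), hdr, value = TRUE)
        if (!length(ln)) return(NULL)
        kv <- strsplit(sub(paste0("^# ", tag, ": "), "", ln), "\t")[[1]]
        parts <- strsplit(kv, "=")
        setNames(as.numeric(vapply(parts, `[`, "", 2)),
                 vapply(parts, `[`, "", 1))[sampleCols]
    }
    BinnedCounts(cnt, bins, libSize = parseKv("libSize"),
                 normFactor = parseKv("normFactor"))
}
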