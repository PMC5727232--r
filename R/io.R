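# Readers and writers for the standard interval formats. rtracklayer does
# the BED coordinate conversion; narrowPeak is BED6+4 with the summit offset
# in the last column (-1 when absent).

.NARROWPEAK_EXTRA <- c(signalValue = "numeric", pValue = "numeric",
                       qValue = "numeric", peak = "integer")

.looksLikeNarrowPeak <- function(path) {
    if (grepl("\\.narrowPeak(\\.gz)?$", path, ignore.case = TRUE)) return(TRUE)
    first <- readLines(path, n = 1L)
    length(first) == 1L && length(strsplit(first, "\t")[[1]]) == 10L
}

#' Read ChIP-Seq peaks (BED3/BED6/narrowPeak)
#'
#' narrowPeak files additionally populate a `summit` metadata column with
#' the point-source offset from the peak start (`NA` when the file records
#' -1), consumed by [centerWindows()] with `useSummit = TRUE`.
#'
#' @param path a BED or narrowPeak file.
#' @return `GRanges` of peaks (1-based closed coordinates).
#' @export
readPeaks <- function(path) {
    if (!file.exists(path)) stop("peak file not found: ", path)
    if (.looksLikeNarrowPeak(path)) {
        gr <- rtracklayer::import(path, format = "BED",
                                  extraCols = .NARROWPEAK_EXTRA)
        mcols(gr)$summit <- ifelse(mcols(gr)$peak < 0L, NA_integer_,
                                   mcols(gr)$peak)
        mcols(gr)$peak <- NULL
    } else {
        gr <- rtracklayer::import(path, format = "BED")
        mcols(gr)$summit <- NA_integer_
    }
    gr
}

#' Read TSS records (BED6 or GFF/GTF)
#'
#' For GFF/GTF input, transcript-level records (`type` transcript or mRNA)
#' are used; the 5' end of each record on its own strand becomes the TSS.
#' For BED6 input the interval is likewise collapsed to its strand-aware 5'
#' end. All records must be stranded.
#'
#' @param path a BED6, GFF3 or GTF file.
#' @return `GRanges` of width-1 TSS positions with strand and a `gene_id`
#'   metadata column.
#' @export
readTSS <- function(path) {
    if (!file.exists(path)) stop("TSS file not found: ", path)
    if (grepl("\\.(gff3?|gtf)(\\.gz)?$", path, ignore.case = TRUE)) {
        gr <- rtracklayer::import(path)
        if ("type" %in% names(mcols(gr))) {
            tx <- gr[as.character(mcols(gr)$type) %in% c("transcript", "mRNA")]
            if (length(tx)) gr <- tx
        }
        ids <- if ("transcript_id" %in% names(mcols(gr)))
            mcols(gr)$transcript_id
        else if ("ID" %in% names(mcols(gr))) mcols(gr)$ID
        else sprintf("tss_%d", seq_along(gr))
    } else {
        gr <- rtracklayer::import(path, format = "BED")
        ids <- if (!is.null(mcols(gr)$name)) mcols(gr)$name
               else sprintf("tss_%d", seq_along(gr))
    }
    if (any(!as.character(strand(gr)) %in% c("+", "-")))
        stop("TSS records must be stranded (+/-): strand defines 'upstream'")
    tss <- GenomicRanges::resize(gr, width = 1L, fix = "start")
    mcols(tss) <- DataFrame(gene_id = as.character(ids))
    tss
}

#' Read a two-column chrom.sizes file
#'
#' @param path tab-separated `chrom<TAB>length` file.
#' @return named numeric vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
    d <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "size"),
                           colClasses = c("character", "numeric"))
    stats::setNames(d$size, d$chrom)
}

#' Write regions as BED6
#'
#' @param regions `GRanges`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeRegionsBed <- function(regions, path) {
    stopifnot(is(regions, "GRanges"))
    gr <- granges(regions)  # drop mcols rtracklayer cannot map to BED
    if (!is.null(names(regions))) names(gr) <- names(regions)
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}
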