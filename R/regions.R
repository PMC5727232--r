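# Region construction: peak-centered windows, promoter proximity,
# peak-vs-peak exclusion, random baseline, sequence extraction.
# All coordinates are 1-based closed (GRanges convention); BED conversion
# happens in the rtracklayer-backed readers/writers (io.R).

.chromSizesFor <- function(gr, chromSizes) {
    lv <- unique(as.character(seqnames(gr)))
    if (is.null(chromSizes)) {
        chromSizes <- seqlengths(gr)
        chromSizes <- chromSizes[!is.na(chromSizes)]
    }
    missing <- setdiff(lv, names(chromSizes))
    if (length(missing))
        stop("missing chromosome size for: ", paste(missing, collapse = ", "))
    chromSizes
}

# midpoint of a GRanges interval in 0-based coordinates: floor((start0+end0)/2)
.center0 <- function(gr) floor((start(gr) - 1 + end(gr)) / 2)

#' Fixed-width windows centered on ChIP-Seq peaks
#'
#' Each peak is replaced by a window of `width` bp centered on the peak
#' midpoint (or on the reported summit when `useSummit = TRUE` and a
#' `summit` metadata column is present). Windows extending past a chromosome
#' end are dropped, not clipped, so all regions share one width; exact
#' duplicate windows are removed, keeping the first occurrence.
#'
#' @param peaks `GRanges` of peaks; a `summit` metadata column (offset from
#'   peak start, `NA` when absent) enables `useSummit`.
#' @param width window width in bp; must be even and positive (default 200).
#' @param useSummit center on `start + summit` where a summit is recorded.
#' @param chromSizes named vector of chromosome lengths; taken from
#'   `seqlengths(peaks)` when `NULL`.
#' @return `GRanges` of distinct `width`-bp windows, with
#'   `metadata(x)$provenance == "chip"`.
#' @export
centerWindows <- function(peaks, width = 200L, useSummit = FALSE,
                          chromSizes = NULL) {
    stopifnot(is(peaks, "GRanges"))
    if (width <= 0 || width %% 2 != 0)
        stop("'width' must be a positive even number of bp")
    if (length(peaks) == 0L)
        return(.emptyRegions(provenance = "chip"))
    chromSizes <- .chromSizesFor(peaks, chromSizes)
    c0 <- .center0(peaks)
    if (useSummit && "summit" %in% names(mcols(peaks))) {
        sm <- mcols(peaks)$summit
        use <- !is.na(sm) & sm >= 0
        c0[use] <- start(peaks)[use] - 1L + sm[use]
    }
    ws <- c0 - width / 2 + 1  # 1-based start
    we <- c0 + width / 2
    ok <- ws >= 1 & we <= chromSizes[as.character(seqnames(peaks))]
    gr <- GRanges(seqnames(peaks)[ok], IRanges(ws[ok], we[ok]))
    if (length(gr)) {
        key <- paste0(as.character(seqnames(gr)), ":", start(gr), "-", end(gr))
        gr <- gr[!duplicated(key)]
    }
    GenomeInfoDb::seqlevels(gr) <- names(chromSizes)
    GenomeInfoDb::seqlengths(gr) <- chromSizes
    metadata(gr)$provenance <- "chip"
    gr
}

.emptyRegions <- function(provenance) {
    gr <- GRanges()
    metadata(gr)$provenance <- provenance
    gr
}

#' Keep regions promoter-proximal to a TSS
#'
#' A region is kept when its midpoint lies within the strand-aware upstream
#' window of at least one TSS: for a `+`-strand TSS at position p the window
#' is `[p - maxUpstream, p]`, mirrored for `-` strand
#' (`mode = "upstream_only"`, the default). `mode = "symmetric"` uses
#' `[p - maxUpstream, p + maxUpstream]` regardless of strand.
#'
#' @param regions `GRanges` of analysis windows.
#' @param tss `GRanges` of width-1 TSS records with strand `+` or `-`
#'   (see [readTSS()]).
#' @param maxUpstream maximum upstream distance in bp (default 1000).
#' @param mode `"upstream_only"` (default) or `"symmetric"`.
#' @return the kept subset of `regions`, order preserved.
#' @export
promoterFilter <- function(regions, tss, maxUpstream = 1000L,
                           mode = c("upstream_only", "symmetric")) {
    mode <- match.arg(mode)
    stopifnot(is(regions, "GRanges"), is(tss, "GRanges"))
    if (length(tss) == 0L)
        stop("empty TSS list: refusing to treat missing annotation as ",
             "'no promoters'")
    sd <- as.character(strand(tss))
    if (any(!sd %in% c("+", "-")))
        stop("all TSS records must have strand '+' or '-'")
    if (any(width(tss) != 1L))
        stop("TSS records must have width 1 (use readTSS())")
    if (length(regions) == 0L) return(regions)

    p0 <- start(tss) - 1L   # 0-based TSS coordinate
    if (mode == "symmetric") {
        ws <- p0 - maxUpstream; we <- p0 + maxUpstream
    } else {
        ws <- ifelse(sd == "+", p0 - maxUpstream, p0)
        we <- ifelse(sd == "+", p0, p0 + maxUpstream)
    }
    windows <- GRanges(seqnames(tss), IRanges(pmax(ws, 0L) + 1L, we + 1L))
    centers <- GRanges(seqnames(regions), IRanges(.center0(regions) + 1L, width = 1L))
    keep <- countOverlaps(centers, windows, ignore.strand = TRUE) > 0L
    out <- regions[keep]
    metadata(out) <- metadata(regions)
    out
}

#' Remove regions overlapping another peak set
#'
#' Drops any region sharing at least 1 bp with any interval in
#' `otherPeaks` (strand ignored); used e.g. to retain Smad4 peaks not
#' overlapped by SP1 or CTCF peaks.
#'
#' @param regions `GRanges` to filter.
#' @param otherPeaks `GRanges` of intervals to exclude against.
#' @return the kept subset of `regions`.
#' @export
excludeOverlapping <- function(regions, otherPeaks) {
    stopifnot(is(regions, "GRanges"), is(otherPeaks, "GRanges"))
    if (length(otherPeaks) == 0L) return(regions)
    out <- subsetByOverlaps(regions, otherPeaks, invert = TRUE,
                            ignore.strand = TRUE)
    metadata(out) <- metadata(regions)
    out
}

#' Random genomic baseline regions
#'
#' Draws `n` fixed-width regions uniformly over all valid start positions,
#' chromosomes weighted by their number of valid starts. Draws whose
#' sequence exceeds `maxNFraction` ambiguous bases are rejected and redrawn.
#' The same seed always yields the identical region list.
#'
#' @param genome a named [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param n number of regions (default 500).
#' @param width region width in bp (default 200).
#' @param seed integer seed (mandatory).
#' @param maxNFraction maximum tolerated fraction of N bases (default 0.1).
#' @param maxRounds redraw rounds before giving up.
#' @return `GRanges` of `n` regions with `metadata(x)$provenance == "baseline"`.
#' @export
sampleBaseline <- function(genome, n = 500L, width = 200L, seed,
                           maxNFraction = 0.1, maxRounds = 50L) {
    if (missing(seed)) stop("'seed' is required for baseline sampling")
    genome <- .asGenome(genome)
    lens <- Biostrings::width(genome)
    valid <- lens - width + 1L
    keep <- valid > 0L
    if (!any(keep))
        stop("no chromosome is at least ", width, " bp long")
    withr::with_seed(seed, {
        draw <- function(m) {
            ci <- sample(which(keep), m, replace = TRUE, prob = valid[keep])
            st <- floor(stats::runif(m) * valid[ci]) + 1L
            GRanges(names(genome)[ci], IRanges(as.integer(st), width = width))
        }
        gr <- draw(n)
        for (round in seq_len(maxRounds)) {
            nfrac <- Biostrings::letterFrequency(
                .extractFromSet(genome, gr), "N") / width
            bad <- as.vector(nfrac) > maxNFraction
            if (!any(bad)) break
            gr[bad] <- draw(sum(bad))
        }
        if (any(bad))
            stop("could not place ", n, " baseline regions with N fraction <= ",
                 maxNFraction, " after ", maxRounds, " redraw rounds (",
                 sum(bad), " still rejected)")
    })
    names(gr) <- sprintf("baseline_%d", seq_len(n))
    GenomeInfoDb::seqlevels(gr) <- names(genome)
    GenomeInfoDb::seqlengths(gr) <- lens
    metadata(gr)$provenance <- "baseline"
    gr
}

.asGenome <- function(genome) {
    if (is.character(genome) && length(genome) == 1L)
        genome <- Biostrings::readDNAStringSet(genome)
    stopifnot(is(genome, "DNAStringSet"))
    if (is.null(names(genome)))
        stop("genome sequences must be named")
    # FASTA headers may carry descriptions; keep the first word
    names(genome) <- sub("\\s.*", "", names(genome))
    genome
}

# Fast per-chromosome extraction from an in-memory genome.
.extractFromSet <- function(genome, regions) {
    if (length(regions) == 0L) return(Biostrings::DNAStringSet())
    out <- vector("list", length(regions))
    for (chr in unique(as.character(seqnames(regions)))) {
        idx <- which(as.character(seqnames(regions)) == chr)
        v <- Biostrings::Views(genome[[chr]],
                               IRanges(start(regions)[idx], end(regions)[idx]))
        out[idx] <- as.list(as(v, "DNAStringSet"))
    }
    do.call(c, lapply(out, Biostrings::DNAStringSet))
}

#' Extract forward-strand region sequences
#'
#' @param genome a named [Biostrings::DNAStringSet], or a path to a FASTA
#'   file (indexed on the fly with [Rsamtools::indexFa()] if needed).
#' @param regions `GRanges`; every region must fall inside its chromosome.
#' @return [Biostrings::DNAStringSet] of uppercase forward-strand sequences,
#'   one per region, order preserved; names are region names or
#'   `chrom:start-end` labels.
#' @export
extractSequences <- function(genome, regions) {
    stopifnot(is(regions, "GRanges"))
    labels <- if (!is.null(names(regions)) && all(nzchar(names(regions))))
        names(regions)
    else sprintf("%s:%d-%d", seqnames(regions), start(regions), end(regions))
    if (is.character(genome) && length(genome) == 1L) {
        if (!file.exists(paste0(genome, ".fai")))
            Rsamtools::indexFa(genome)
        fa <- Rsamtools::FaFile(genome)
        lens <- GenomeInfoDb::seqlengths(GenomeInfoDb::seqinfo(fa))
        .checkBounds(regions, lens, labels)
        seqs <- Biostrings::getSeq(fa, regions)
    } else {
        genome <- .asGenome(genome)
        lens <- stats::setNames(Biostrings::width(genome), names(genome))
        .checkBounds(regions, lens, labels)
        seqs <- .extractFromSet(genome, regions)
    }
    names(seqs) <- labels
    seqs
}

.checkBounds <- function(regions, lens, labels) {
    chr <- as.character(seqnames(regions))
    missing <- !chr %in% names(lens)
    if (any(missing))
        stop("chromosome not found in genome for region(s): ",
             paste(utils::head(labels[missing], 5L), collapse = ", "))
    oob <- start(regions) < 1L | end(regions) > lens[chr]
    if (any(oob))
        stop("region(s) outside chromosome bounds: ",
             paste(utils::head(labels[oob], 5L), collapse = ", "))
    invisible(TRUE)
}
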