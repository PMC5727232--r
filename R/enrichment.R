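# Per-region motif profiles and the statistics computed from them:
# fold enrichment vs baseline, cluster distributions, co-occurrence,
# the MH1 footprint-capacity model, and the EMSA probe tiler.

# Vectorised occurrence counting of one IUPAC pattern over many sequences.
# Minus-strand occurrences are found by matching revcomp(pattern) forward.
.countPattern <- function(seqs, charSeqs, pattern, strand, notBase) {
    k <- nchar(pattern)
    query <- if (strand == "+") pattern else revCompIupac(pattern)
    m <- Biostrings::vmatchPattern(query, seqs, fixed = "subject")
    if (is.na(notBase))
        return(S4Vectors::elementNROWS(m))
    si <- Biostrings::startIndex(m)
    vapply(seq_along(charSeqs), function(i) {
        st <- si[[i]]
        if (is.null(st)) return(0L)
        sum(.contextOK(charSeqs[[i]], st, k, strand, notBase))
    }, integer(1))
}

.countPanel <- function(seqs, charSeqs, panel, strands) {
    want <- if (strands == "both") c("+", "-") else strands
    notBase <- contextRule(panel)
    pats <- as.character(panelPatterns(panel))
    per <- vapply(pats, function(p) {
        Reduce(`+`, lapply(want, function(sd)
            .countPattern(seqs, charSeqs, p, sd, notBase)))
    }, integer(length(seqs)))
    if (length(seqs) == 1L) per <- matrix(per, nrow = 1L,
                                          dimnames = list(NULL, pats))
    per
}

#' Per-region motif profiles
#'
#' Scans every region sequence for every panel and assembles the counts
#' into a [MotifProfile-class] (a `RangedSummarizedExperiment`): one pooled
#' column per panel plus `panel.pattern` columns for multi-pattern panels.
#'
#' @param seqs a [Biostrings::DNAStringSet] (or character vector) of region
#'   sequences, all of one width.
#' @param panels a [MotifPanel-class], list of panels, or character vector of
#'   built-in panel names; defaults to FIVE_GC, CAGAC, AGAC, DAGAC.
#' @param strands `"both"` (default), `"+"` or `"-"`.
#' @param regions optional `GRanges` giving the genomic coordinates of the
#'   regions (used as `rowRanges`); synthesised from sequence names if absent.
#' @return a [MotifProfile-class].
#' @examples
#' prof <- profileRegions(c(r1 = "GGCGCCAAAA", r2 = "AAAAAAAAAA"),
#'                        builtinPanel("FIVE_GC"))
#' panelCounts(prof, "FIVE_GC")
#' @export
profileRegions <- function(seqs, panels = builtinPanels(), strands = "both",
                           regions = NULL) {
    strands <- match.arg(strands, c("both", "+", "-"))
    if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
    stopifnot(is(seqs, "DNAStringSet"))
    if (length(seqs) == 0L) stop("no region sequences supplied")
    w <- unique(Biostrings::width(seqs))
    if (length(w) != 1L)
        stop("ragged sequence lengths: all regions must share one width ",
             "(found ", paste(w, collapse = ", "), ")")
    if (is(panels, "MotifPanel")) panels <- list(panels)
    if (is.character(panels)) panels <- lapply(panels, builtinPanel)
    names(panels) <- vapply(panels, panelName, "")
    if (anyDuplicated(names(panels))) stop("duplicate panel names")

    charSeqs <- as.character(seqs)
    cols <- list()
    for (p in panels) {
        per <- .countPanel(seqs, charSeqs, p, strands)
        cols[[panelName(p)]] <- as.integer(rowSums(per))
        if (ncol(per) > 1L)
            for (j in seq_len(ncol(per)))
                cols[[paste0(panelName(p), ".", colnames(per)[j])]] <-
                    as.integer(per[, j])
    }
    mat <- do.call(cbind, cols)
    if (is.null(regions)) {
        nm <- if (!is.null(names(seqs))) names(seqs)
              else sprintf("region_%d", seq_along(seqs))
        regions <- GRanges(nm, IRanges(1L, w))
    }
    stopifnot(length(regions) == length(seqs))
    rownames(mat) <- NULL
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = mat), rowRanges = regions,
        metadata = list(panels = panels, strands = strands))
    new("MotifProfile", se)
}

#' Extract per-region counts for one panel
#'
#' @param x a [MotifProfile-class].
#' @param panel a panel (or `panel.pattern`) column name.
#' @return integer vector of counts, one per region.
#' @rdname panelCounts
#' @export
setMethod("panelCounts", "MotifProfile", function(x, panel) {
    m <- SummarizedExperiment::assay(x, "counts")
    if (!panel %in% colnames(m))
        stop("unknown panel '", panel, "'; available: ",
             paste(colnames(m), collapse = ", "))
    as.integer(m[, panel])
})

setMethod("show", "MotifProfile", function(object) {
    m <- SummarizedExperiment::assay(object, "counts")
    cat("MotifProfile with", nrow(m), "regions x", ncol(m), "count columns\n")
    cat("panels:", paste(names(S4Vectors::metadata(object)$panels),
                         collapse = ", "),
        "| strands:", S4Vectors::metadata(object)$strands, "\n")
    pooled <- names(S4Vectors::metadata(object)$panels)
    pooled <- pooled[pooled %in% colnames(m)]
    if (length(pooled))
        print(round(colMeans(m[, pooled, drop = FALSE]), 3))
})

#' Fold enrichment of a motif panel over the baseline
#'
#' The enrichment statistic is the ratio of per-region means:
#' `mean(chip counts) / mean(baseline counts)`. A zero baseline mean is an
#' error (enrichment undefined), never infinity. An optional bootstrap over
#' regions (clearly an extra beyond the ratio itself) attaches a percentile
#' confidence interval.
#'
#' @param chip,baseline [MotifProfile-class] objects for the bound and
#'   baseline region sets.
#' @param panel panel column to compare.
#' @param nBoot bootstrap replicates (0 = none).
#' @param seed seed for the bootstrap (required when `nBoot > 0`).
#' @param level confidence level for the bootstrap interval.
#' @return an [EnrichmentResult-class].
#' @export
foldEnrichment <- function(chip, baseline, panel, nBoot = 0L, seed = NULL,
                           level = 0.95) {
    cc <- panelCounts(chip, panel)
    bb <- panelCounts(baseline, panel)
    if (length(cc) == 0L || length(bb) == 0L)
        stop("both profiles must be non-empty")
    mb <- mean(bb)
    if (mb == 0)
        stop("baseline mean count for panel '", panel,
             "' is zero: fold enrichment is undefined")
    ci <- numeric(0)
    if (nBoot > 0L) {
        if (is.null(seed)) stop("'seed' is required when nBoot > 0")
        ci <- withr::with_seed(seed, {
            folds <- vapply(seq_len(nBoot), function(i) {
                m2 <- mean(sample(bb, replace = TRUE))
                if (m2 == 0) NA_real_
                else mean(sample(cc, replace = TRUE)) / m2
            }, numeric(1))
            a <- (1 - level) / 2
            unname(stats::quantile(folds, c(a, 1 - a), na.rm = TRUE))
        })
    }
    new("EnrichmentResult", panel = panel, meanChip = mean(cc),
        meanBaseline = mb, fold = mean(cc) / mb,
        nChip = length(cc), nBaseline = length(bb), ci = ci)
}

#' @rdname EnrichmentResult-class
#' @export
setMethod("enrichmentFold", "EnrichmentResult", function(x) x@fold)

setMethod("show", "EnrichmentResult", function(object) {
    cat(sprintf(
        "EnrichmentResult '%s': fold %.3f (chip mean %.3f, n=%d; baseline mean %.3f, n=%d)\n",
        object@panel, object@fold, object@meanChip, object@nChip,
        object@meanBaseline, object@nBaseline))
    if (length(object@ci) == 2L)
        cat(sprintf("  bootstrap CI [%.3f, %.3f]\n", object@ci[1], object@ci[2]))
})

#' @export
#' @method as.data.frame EnrichmentResult
as.data.frame.EnrichmentResult <- function(x, ...) {
    data.frame(panel = x@panel, mean_chip = x@meanChip,
               mean_baseline = x@meanBaseline, fold = x@fold,
               n_chip = x@nChip, n_baseline = x@nBaseline,
               stringsAsFactors = FALSE)
}

#' Distribution of per-region motif cluster sizes
#'
#' Classifies regions by their panel motif count into 0, 1, ...,
#' `threshold - 1`, and `>= threshold` (default 3, the clustering cutoff
#' used throughout the analyses).
#'
#' @param profile a [MotifProfile-class].
#' @param panel panel column name.
#' @param threshold top bin cutoff (default 3).
#' @return a [ClusterDistribution-class].
#' @export
clusterDistribution <- function(profile, panel, threshold = 3L) {
    threshold <- as.integer(threshold)
    stopifnot(threshold >= 1L)
    x <- panelCounts(profile, panel)
    if (length(x) == 0L) stop("profile is empty")
    tallies <- c(vapply(0:(threshold - 1L), function(b) sum(x == b), integer(1)),
                 sum(x >= threshold))
    names(tallies) <- c(as.character(0:(threshold - 1L)),
                        paste0(">=", threshold))
    new("ClusterDistribution", panel = panel, threshold = threshold,
        tallies = tallies, fractions = tallies / length(x), n = length(x))
}

#' @rdname ClusterDistribution-class
#' @export
setMethod("clusterFractions", "ClusterDistribution", function(x) x@fractions)

#' @rdname ClusterDistribution-class
#' @export
setMethod("clusterTallies", "ClusterDistribution", function(x) x@tallies)

setMethod("show", "ClusterDistribution", function(object) {
    cat("ClusterDistribution '", object@panel, "' over ", object@n,
        " regions:\n", sep = "")
    print(round(object@fractions, 4))
})

#' @export
#' @method as.data.frame ClusterDistribution
as.data.frame.ClusterDistribution <- function(x, ...) {
    data.frame(panel = x@panel, bin = names(x@tallies),
               regions = as.integer(x@tallies), fraction = unname(x@fractions),
               stringsAsFactors = FALSE)
}

#' Fraction of regions where two panels co-occur
#'
#' E.g. the fraction of promoter regions carrying a cluster of three or
#' more 5GC elements together with at least one CAGAC.
#'
#' @param profile a [MotifProfile-class].
#' @param panelA,panelB panel column names.
#' @param minA,minB minimum counts required of each panel.
#' @return the fraction of regions with `countA >= minA & countB >= minB`.
#' @export
cooccurrenceFraction <- function(profile, panelA, minA = 3L,
                                 panelB, minB = 1L) {
    a <- panelCounts(profile, panelA)
    b <- panelCounts(profile, panelB)
    mean(a >= minA & b >= minB)
}

#' Maximum simultaneous MH1 footprint occupancy
#'
#' Each motif hit anchors a footprint of `footprint` bp at its start (the
#' 5-bp contact area of one MH1 domain extends to six base pairs once
#' backbone contacts are included). The site capacity is the maximum number
#' of mutually non-overlapping footprints, found by earliest-end greedy
#' selection, which is optimal for unit-weight interval scheduling.
#'
#' @param hits `GRanges` of hits on one sequence (from [scanMotifs()]), or
#'   an integer vector of hit start positions.
#' @param footprint footprint width in bp (default 6); must be at least the
#'   motif width.
#' @return integer capacity.
#' @examples
#' siteCapacity(c(1, 5, 13), footprint = 6)  # 2
#' @export
siteCapacity <- function(hits, footprint = 6L) {
    if (is(hits, "GRanges")) {
        if (length(hits) &&
            length(unique(as.character(seqnames(hits)))) > 1L)
            stop("hits must all lie on one sequence")
        if (length(hits) && footprint < max(width(hits)))
            stop("'footprint' must be at least the motif length")
        starts <- start(hits)
    } else starts <- as.numeric(hits)
    if (length(starts) == 0L) return(0L)
    ends <- starts + footprint - 1
    o <- order(ends)
    lastEnd <- -Inf
    n <- 0L
    for (i in o) {
        if (starts[i] > lastEnd) {
            n <- n + 1L
            lastEnd <- ends[i]
        }
    }
    n
}

#' Design tiling EMSA probes over a segment
#'
#' Slides a fixed-length window (default 20-bp duplex) across the segment in
#' fixed steps (default 2 bp), the design used to narrow down binding motifs
#' within GC-rich promoter segments.
#'
#' @param segment DNA string of at least `probeLen` bp.
#' @param probeLen probe (duplex) length in bp, default 20.
#' @param step offset between consecutive probes in bp, default 2.
#' @return `data.frame` with `offset` (0-based offset of the probe in the
#'   segment) and `sequence` (forward-strand probe; duplex implied).
#' @examples
#' nrow(designTilingProbes(strrep("A", 30)))  # 6 probes at offsets 0..10
#' @export
designTilingProbes <- function(segment, probeLen = 20L, step = 2L) {
    s <- toupper(as.character(segment))
    stopifnot(length(s) == 1L)
    L <- nchar(s)
    if (L < probeLen)
        stop("segment (", L, " bp) is shorter than the probe length (",
             probeLen, " bp)")
    if (step < 1L) stop("'step' must be >= 1")
    offsets <- seq.int(0L, L - as.integer(probeLen), by = as.integer(step))
    data.frame(offset = offsets,
               sequence = substring(s, offsets + 1L, offsets + probeLen),
               stringsAsFactors = FALSE)
}

#' Write tiling probes as TSV and/or FASTA
#'
#' @param probes output of [designTilingProbes()].
#' @param tsv,fasta output paths (either may be `NULL`).
#' @return invisibly, the written paths.
#' @export
writeTilingProbes <- function(probes, tsv = NULL, fasta = NULL) {
    written <- character(0)
    if (!is.null(tsv)) {
        utils::write.table(probes, tsv, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        written <- c(written, tsv)
    }
    if (!is.null(fasta)) {
        ss <- Biostrings::DNAStringSet(probes$sequence)
        names(ss) <- sprintf("probe_offset_%d", probes$offset)
        Biostrings::writeXStringSet(ss, fasta)
        written <- c(written, fasta)
    }
    invisible(written)
}
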