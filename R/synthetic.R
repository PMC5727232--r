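# Synthetic study generator: an i.i.d. background genome with planted
# 5GC-panel motifs in non-overlapping "bound" regions, plus ChIP-like peaks
# and TSS annotation, and the analytic background expectation used as a
# test oracle.

#' Construct a SyntheticSpec
#'
#' Defaults describe the study conditions emulated throughout the package:
#' 200-bp regions, 1755 bound promoter-proximal regions, a genome-typical
#' GC fraction of 0.41, three planted 5GC-panel motifs per bound region
#' (uniform over the four patterns, either strand), 20-bp peak jitter, and
#' every bound region placed within 1000 bp upstream of a TSS.
#'
#' @param chromLengths named chromosome lengths (bp).
#' @param gcFraction background GC fraction; P(G)=P(C)=gcFraction/2.
#' @param nBoundRegions number of bound regions.
#' @param regionWidth bound-region width (bp).
#' @param plantRate planted motifs per bound region (fixed count, or
#'   Poisson mean when `plantDistribution = "poisson"`).
#' @param plantDistribution `"fixed"` (default) or `"poisson"`.
#' @param motifWeights named sampling probabilities over planted patterns.
#' @param plantStrandProb probability a planted motif goes on the minus strand.
#' @param peakJitterSd SD of the Normal peak-center displacement (bp).
#' @param promoterFraction fraction of bound regions given an upstream TSS.
#' @param tssUpstream maximum distance of a TSS downstream of a bound-region
#'   center (bp).
#' @param seed integer seed governing all randomness of the generator.
#' @return a validated [SyntheticSpec-class].
#' @export
syntheticSpec <- function(chromLengths = c(chrS1 = 1500000, chrS2 = 1000000),
                          gcFraction = 0.41,
                          nBoundRegions = 1755,
                          regionWidth = 200,
                          plantRate = 3,
                          plantDistribution = c("fixed", "poisson"),
                          motifWeights = c(GGCGC = 0.25, GGCGG = 0.25,
                                           GGCCG = 0.25, GGCTG = 0.25),
                          plantStrandProb = 0.5,
                          peakJitterSd = 20,
                          promoterFraction = 1.0,
                          tssUpstream = 1000,
                          seed = 101) {
    plantDistribution <- match.arg(plantDistribution)
    obj <- new("SyntheticSpec", chromLengths = chromLengths,
               gcFraction = gcFraction, nBoundRegions = nBoundRegions,
               regionWidth = regionWidth, plantRate = plantRate,
               plantDistribution = plantDistribution,
               motifWeights = motifWeights,
               plantStrandProb = plantStrandProb,
               peakJitterSd = peakJitterSd,
               promoterFraction = promoterFraction,
               tssUpstream = tssUpstream, seed = seed)
    validObject(obj)
    obj
}

setMethod("show", "SyntheticSpec", function(object) {
    cat("SyntheticSpec:", length(object@chromLengths), "chromosome(s),",
        sum(object@chromLengths), "bp total, GC", object@gcFraction, "\n")
    cat("  ", object@nBoundRegions, " bound regions of ", object@regionWidth,
        " bp, plant rate ", object@plantRate, " (", object@plantDistribution,
        "), promoter fraction ", object@promoterFraction, ", seed ",
        object@seed, "\n", sep = "")
})

# margin kept free at each chromosome end so that recentered windows,
# jittered peaks and upstream TSS records always stay in bounds
.edgeMargin <- function(spec) as.integer(spec@regionWidth + spec@tssUpstream + 100)

# proportional allocation with largest-remainder rounding
.allocate <- function(n, weights) {
    if (n == 0L) return(integer(length(weights)))
    raw <- n * weights / sum(weights)
    out <- floor(raw)
    rem <- n - sum(out)
    if (rem > 0) {
        o <- order(raw - out, decreasing = TRUE)
        out[o[seq_len(rem)]] <- out[o[seq_len(rem)]] + 1
    }
    as.integer(out)
}

# n non-overlapping width-w 0-based starts uniformly in [lo, hi - w]
.placeNonOverlapping <- function(n, w, lo, hi) {
    if (n == 0L) return(integer(0))
    slack <- (hi - lo) - n * w
    if (slack < 0) stop("cannot place ", n, " non-overlapping regions of ",
                        w, " bp in ", hi - lo, " bp of usable sequence")
    u <- sort(as.integer(floor(stats::runif(n) * (slack + 1))))
    lo + u + (seq_len(n) - 1L) * w
}

#' Generate a synthetic genome with planted motifs
#'
#' Background bases are drawn i.i.d. with the requested GC fraction. Bound
#' regions are placed mutually non-overlapping (clear of chromosome ends),
#' and within each, the requested number of panel motifs is written at
#' uniformly drawn non-overlapping offsets, on the minus strand with
#' probability `plantStrandProb` (written as the reverse complement on the
#' forward sequence). A placement is redrawn on collision — with another
#' plant, with a panel hit already present in the background (which
#' overwriting would destroy), or when a plant/background junction would
#' spell out a new accidental panel hit — so each bound region carries
#' exactly its planted motifs plus the untouched background occurrences,
#' and planted counts add to the background rate without bias. Identical
#' seeds give byte-identical output.
#'
#' @param spec a [SyntheticSpec-class].
#' @return a list with `genome` ([Biostrings::DNAStringSet]), `bound`
#'   (`GRanges` of bound regions with an `nPlanted` column), `truth`
#'   (`GRanges` of planted motifs with `pattern`, strand, and `region`
#'   columns), and the `spec`.
#' @export
generateGenome <- function(spec) {
    validObject(spec)
    g <- spec@gcFraction
    w <- as.integer(spec@regionWidth)
    patW <- unique(nchar(names(spec@motifWeights)))
    margin <- .edgeMargin(spec)
    n <- as.integer(spec@nBoundRegions)
    cl <- spec@chromLengths
    if (spec@plantDistribution == "fixed" && spec@plantRate * patW > w)
        stop("region width ", w, " bp cannot hold ", spec@plantRate,
             " non-overlapping ", patW, "-bp motifs")

    withr::with_seed(as.integer(spec@seed), {
        baseProbs <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
        chroms <- lapply(cl, function(L)
            sample(names(baseProbs), L, replace = TRUE, prob = baseProbs))

        usable <- pmax(cl - 2 * margin, 0)
        nPer <- .allocate(n, usable)
        if (any(nPer * w > usable))
            stop("chromosomes too short to hold ", n,
                 " non-overlapping bound regions (increase chromLengths)")

        boundList <- list(); truthList <- list()
        regId <- 0L
        for (ci in seq_along(cl)) {
            starts0 <- .placeNonOverlapping(nPer[ci], w, margin,
                                            as.integer(cl[ci]) - margin)
            if (!length(starts0)) next
            chrom <- names(cl)[ci]
            nPlanted <- integer(length(starts0))
            pos0All <- integer(0); patAll <- character(0)
            negAll <- logical(0); regAll <- character(0)
            oriented <- unique(c(names(spec@motifWeights),
                                 .fastRevComp(names(spec@motifWeights))))
            for (ri in seq_along(starts0)) {
                regId <- regId + 1L
                k <- .drawPlantCount(spec, patW, w)
                nPlanted[ri] <- k
                if (k == 0L) next
                regionChars <- chroms[[ci]][(starts0[ri] + 1):(starts0[ri] + w)]
                pl <- .plantRegion(spec, regionChars, k, patW, w, oriented)
                pos0All <- c(pos0All, starts0[ri] + pl$offs)
                patAll <- c(patAll, pl$pats)
                negAll <- c(negAll, pl$neg)
                regAll <- c(regAll, rep(sprintf("bound_%d", regId), k))
            }
            if (length(pos0All)) {
                fwdSeq <- ifelse(negAll, .fastRevComp(patAll), patAll)
                # one vectorised write per chromosome
                idx <- rep(pos0All, each = patW) +
                    rep(seq_len(patW), length(pos0All))
                chroms[[ci]][idx] <- unlist(strsplit(fwdSeq, ""),
                                            use.names = FALSE)
                truthList[[length(truthList) + 1L]] <- data.frame(
                    chrom = chrom, start = pos0All + 1L,
                    end = pos0All + patW,
                    strand = ifelse(negAll, "-", "+"),
                    pattern = patAll, region = regAll,
                    stringsAsFactors = FALSE)
            }
            boundList[[chrom]] <- data.frame(
                chrom = chrom, start = starts0 + 1L, end = starts0 + w,
                nPlanted = nPlanted,
                name = sprintf("bound_%d", regId - length(starts0) +
                                   seq_along(starts0)),
                stringsAsFactors = FALSE)
        }
        genome <- Biostrings::DNAStringSet(
            vapply(chroms, paste, character(1), collapse = ""))
        names(genome) <- names(cl)
    })

    boundDf <- if (length(boundList)) do.call(rbind, boundList)
               else data.frame(chrom = character(), start = integer(),
                               end = integer(), nPlanted = integer(),
                               name = character())
    sq <- Seqinfo(names(cl), as.integer(cl))
    bound <- GRanges(factor(boundDf$chrom, names(cl)),
                     IRanges(boundDf$start, boundDf$end),
                     nPlanted = boundDf$nPlanted, seqinfo = sq)
    names(bound) <- boundDf$name
    truthDf <- if (length(truthList)) do.call(rbind, truthList)
               else data.frame(chrom = character(), start = integer(),
                               end = integer(), strand = character(),
                               pattern = character(), region = character())
    truth <- GRanges(factor(truthDf$chrom, names(cl)),
                     IRanges(truthDf$start, truthDf$end),
                     strand = truthDf$strand, pattern = truthDf$pattern,
                     region = truthDf$region, seqinfo = sq)
    list(genome = genome, bound = bound, truth = truth, spec = spec)
}

.drawPlantCount <- function(spec, patW, w) {
    if (spec@plantDistribution == "fixed") return(as.integer(spec@plantRate))
    maxK <- floor(w / patW)
    repeat {
        k <- stats::rpois(1L, spec@plantRate)
        if (k <= maxK) return(as.integer(k))
    }
}

# k non-overlapping 0-based offsets within a region; redraw on collision
.drawOffsets <- function(k, w, patW) {
    repeat {
        offs <- sort(sample.int(w - patW + 1L, k, replace = TRUE) - 1L)
        if (k == 1L || all(diff(offs) >= patW)) return(offs)
    }
}

# all window strings of width patW in a character string
.windowStrings <- function(seqChar, patW) {
    L <- nchar(seqChar)
    if (L < patW) return(character(0))
    substring(seqChar, 1:(L - patW + 1L), patW:L)
}

# strand-aware occurrence count: a window matching both a forward pattern
# and the reverse complement of one counts twice, as a scanner reports
.literalCount <- function(wins, fwdSet, revSet)
    sum(wins %in% fwdSet) + sum(wins %in% revSet)

# character-level reverse complement of literal A/C/G/T strings (hot path)
.fastRevComp <- function(x)
    vapply(strsplit(chartr("ACGT", "TGCA", x), ""),
           function(ch) paste(rev(ch), collapse = ""), "",
           USE.NAMES = FALSE)

# Draw a placement of k motifs into one region. A draw is redrawn when the
# plants (i) overlap each other, (ii) overlap a panel hit already present in
# the background sequence (which planting would destroy), or (iii) create a
# new panel hit at a plant/background junction. Under this rule the final
# region carries exactly k planted hits plus the untouched background hits,
# so the planted count adds to the background rate without bias.
.plantRegion <- function(spec, regionChars, k, patW, w, oriented,
                         maxTries = 1000L) {
    fwdSet <- names(spec@motifWeights)
    revSet <- .fastRevComp(fwdSet)
    revOf <- stats::setNames(revSet, fwdSet)
    wins <- .windowStrings(paste(regionChars, collapse = ""), patW)
    bgOffs <- which(wins %in% oriented) - 1L
    bgCount <- .literalCount(wins, fwdSet, revSet)
    for (try in seq_len(maxTries)) {
        offs <- .drawOffsets(k, w, patW)
        if (length(bgOffs) &&
            any(abs(outer(offs, bgOffs, "-")) < patW)) next
        pats <- sample(names(spec@motifWeights), k, replace = TRUE,
                       prob = spec@motifWeights)
        neg <- stats::runif(k) < spec@plantStrandProb
        fwd <- ifelse(neg, unname(revOf[pats]), pats)
        cand <- regionChars
        idx <- rep(offs, each = patW) + rep(seq_len(patW), k)
        cand[idx] <- unlist(strsplit(fwd, ""), use.names = FALSE)
        candWins <- .windowStrings(paste(cand, collapse = ""), patW)
        plantContrib <- sum(fwd %in% fwdSet) + sum(fwd %in% revSet)
        if (.literalCount(candWins, fwdSet, revSet) == bgCount + plantContrib)
            return(list(offs = offs, pats = pats, neg = neg))
    }
    stop("could not place ", k, " motifs in a ", w,
         "-bp region without side effects after ", maxTries, " tries")
}

#' Emit peak and TSS annotation for a synthetic genome
#'
#' One peak per bound region, its center displaced by Normal(0,
#' `peakJitterSd`) rounded to integer and clipped to the chromosome. For
#' `promoterFraction` of the bound regions a TSS is placed (on a random
#' strand) such that the region center lies uniformly 0 to `tssUpstream` bp
#' upstream of it.
#'
#' @param spec the [SyntheticSpec-class] used for generation.
#' @param sim output of [generateGenome()].
#' @return list with `peaks` (`GRanges`) and `tss` (width-1 stranded
#'   `GRanges` with `gene_id`).
#' @export
emitAnnotation <- function(spec, sim) {
    bound <- sim$bound
    n <- length(bound)
    w <- as.integer(spec@regionWidth)
    cl <- spec@chromLengths
    withr::with_seed(as.integer(spec@seed) + 1L, {
        c0 <- .center0(bound) + as.integer(round(stats::rnorm(n, 0, spec@peakJitterSd)))
        ps <- pmax(c0 - w / 2 + 1, 1)
        pe <- pmin(c0 + w / 2, cl[as.character(seqnames(bound))])
        peaks <- GRanges(seqnames(bound), IRanges(ps, pe),
                         name = sprintf("peak_%d", seq_len(n)),
                         summit = rep(NA_integer_, n))
        m <- round(spec@promoterFraction * n)
        idx <- if (m > 0) sort(sample.int(n, m)) else integer(0)
        str <- sample(c("+", "-"), m, replace = TRUE)
        u <- sample.int(spec@tssUpstream + 1L, m, replace = TRUE) - 1L
        rc0 <- .center0(bound)[idx]
        p0 <- ifelse(str == "+", rc0 + u, rc0 - u)
        tss <- GRanges(seqnames(bound)[idx], IRanges(p0 + 1L, width = 1L),
                       strand = str,
                       gene_id = sprintf("gene_%05d", idx))
    })
    sq <- Seqinfo(names(cl), as.integer(cl))
    GenomeInfoDb::seqlevels(peaks) <- names(cl)
    GenomeInfoDb::seqinfo(peaks) <- sq
    GenomeInfoDb::seqlevels(tss) <- names(cl)
    GenomeInfoDb::seqinfo(tss) <- sq
    list(peaks = peaks, tss = tss)
}

#' Analytic expected background motif count per region
#'
#' First-order expectation of panel occurrences in a `width`-bp region of
#' i.i.d. sequence with GC fraction g (P(G)=P(C)=g/2, P(A)=P(T)=(1-g)/2):
#' the sum over patterns, strands and window offsets of the per-window match
#' probability; overlaps between windows are ignored. A panel 5'-context
#' rule is honoured: interior windows carry an extra factor
#' P(preceding base != disallowed), edge windows do not.
#'
#' @param panel a [MotifPanel-class] or built-in panel name.
#' @param width region width in bp.
#' @param gcFraction background GC fraction.
#' @param strands `"both"` (default), `"+"` or `"-"`.
#' @return expected count (numeric).
#' @examples
#' expectedBackgroundCount("FIVE_GC", 200, 0.5)  # 2 * 196 * 4 / 1024
#' @export
expectedBackgroundCount <- function(panel, width = 200L, gcFraction = 0.5,
                                    strands = "both") {
    strands <- match.arg(strands, c("both", "+", "-"))
    if (is.character(panel)) panel <- builtinPanel(panel)
    g <- gcFraction
    baseP <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
    map <- Biostrings::IUPAC_CODE_MAP
    pLetter <- function(l) sum(baseP[strsplit(map[[l]], "")[[1]]])
    pMatch <- function(pat) prod(vapply(strsplit(pat, "")[[1]], pLetter, 1))
    k <- patternWidth(panel)
    if (width < k) return(0)
    notBase <- contextRule(panel)
    want <- if (strands == "both") c("+", "-") else strands
    total <- 0
    for (pat in as.character(panelPatterns(panel))) {
        for (sd in want) {
            p <- pMatch(if (sd == "+") pat else revCompIupac(pat))
            if (is.na(notBase)) {
                total <- total + (width - k + 1) * p
            } else {
                pOK <- 1 - baseP[[notBase]]
                # one window sits at the sequence edge and needs no context
                total <- total + (width - k) * pOK * p + p
            }
        }
    }
    total
}

#' Write a complete synthetic dataset to disk
#'
#' Emits `genome.fa` (+ `.fai` index), `peaks.bed`, `tss.bed`,
#' `chrom.sizes`, `truth.tsv` and `spec.yaml` into `outDir`; the files are
#' consumed directly by [runEnrich()].
#'
#' @param spec a [SyntheticSpec-class].
#' @param outDir output directory (created if needed).
#' @return invisibly, a named list of written paths plus the in-memory
#'   simulation (`sim`, `annotation`).
#' @export
runSimulate <- function(spec, outDir) {
    validObject(spec)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    sim <- generateGenome(spec)
    ann <- emitAnnotation(spec, sim)
    paths <- list(
        genome = file.path(outDir, "genome.fa"),
        peaks = file.path(outDir, "peaks.bed"),
        tss = file.path(outDir, "tss.bed"),
        chromSizes = file.path(outDir, "chrom.sizes"),
        truth = file.path(outDir, "truth.tsv"),
        spec = file.path(outDir, "spec.yaml"))
    Biostrings::writeXStringSet(sim$genome, paths$genome)
    Rsamtools::indexFa(paths$genome)
    .exportBed(ann$peaks, paths$peaks)
    .exportBed(ann$tss, paths$tss)
    utils::write.table(
        data.frame(names(spec@chromLengths), as.integer(spec@chromLengths)),
        paths$chromSizes, sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    truthDf <- as.data.frame(sim$truth)[, c("seqnames", "start", "end",
                                            "strand", "pattern", "region")]
    names(truthDf)[1] <- "chrom"
    utils::write.table(truthDf, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    yaml::write_yaml(specAsList(spec), paths$spec)
    message("synthetic dataset written to ", outDir)
    invisible(c(paths, list(sim = sim, annotation = ann)))
}

.exportBed <- function(gr, path) {
    if (length(gr) == 0L) {
        file.create(path)
        return(invisible(path))
    }
    out <- gr
    if ("name" %in% names(mcols(out))) names(out) <- mcols(out)$name
    else if ("gene_id" %in% names(mcols(out))) names(out) <- mcols(out)$gene_id
    mcols(out) <- NULL
    rtracklayer::export(out, path, format = "BED")
    invisible(path)
}

#' @rdname syntheticSpec
#' @param spec a `SyntheticSpec`.
#' @export
specAsList <- function(spec) {
    list(chrom_lengths = as.list(spec@chromLengths),
         gc_fraction = spec@gcFraction,
         n_bound_regions = spec@nBoundRegions,
         region_width = spec@regionWidth,
         plant_rate = spec@plantRate,
         plant_distribution = spec@plantDistribution,
         motif_weights = as.list(spec@motifWeights),
         plant_strand_prob = spec@plantStrandProb,
         peak_jitter_sd = spec@peakJitterSd,
         promoter_fraction = spec@promoterFraction,
         tss_upstream = spec@tssUpstream,
         seed = spec@seed)
}
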