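#' @importFrom methods new validObject is as slot setValidity show
#' @import BiocGenerics
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

.IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                    "B", "D", "H", "V", "N")

#' MotifPanel: a named panel of fixed-length IUPAC DNA patterns
#'
#' A `MotifPanel` bundles one or more IUPAC patterns of equal length under a
#' panel name, optionally with a 5'-context rule: `fivePrimeNot = "C"` means a
#' match only counts when the base immediately 5' of it (on the match's
#' strand) is not C, with a sequence edge treated as satisfying the rule.
#' The context rule is how the DAGAC panel (AGAC not preceded by C) shares a
#' single scan with plain AGAC.
#'
#' @slot name single character label for the panel.
#' @slot patterns a [Biostrings::DNAStringSet] of equal-width IUPAC patterns.
#' @slot fivePrimeNot `NA` or a single base that must *not* precede a match.
#' @seealso [motifPanel()], [builtinPanel()], [scanMotifs()]
#' @exportClass MotifPanel
setClass("MotifPanel",
    representation(name = "character",
                   patterns = "DNAStringSet",
                   fivePrimeNot = "character"),
    prototype(fivePrimeNot = NA_character_))

setValidity("MotifPanel", function(object) {
    msg <- character(0)
    if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
        msg <- c(msg, "'name' must be a single non-empty string")
    if (length(object@patterns) < 1L)
        msg <- c(msg, "panel must contain at least one pattern")
    else {
        w <- Biostrings::width(object@patterns)
        if (length(unique(w)) != 1L)
            msg <- c(msg, "all patterns in a panel must have the same length")
        if (any(w < 1L))
            msg <- c(msg, "patterns must be non-empty")
        chars <- unique(unlist(strsplit(as.character(object@patterns), "")))
        if (!all(chars %in% .IUPAC_LETTERS))
            msg <- c(msg, "patterns must use IUPAC nucleotide codes only")
    }
    if (length(object@fivePrimeNot) != 1L)
        msg <- c(msg, "'fivePrimeNot' must be length 1 (use NA for none)")
    else if (!is.na(object@fivePrimeNot) &&
             !object@fivePrimeNot %in% c("A", "C", "G", "T"))
        msg <- c(msg, "'fivePrimeNot' must be NA or one of A/C/G/T")
    if (length(msg)) msg else TRUE
})

#' MotifProfile: per-region motif counts
#'
#' Extends [SummarizedExperiment::RangedSummarizedExperiment]: rows are
#' regions (with their coordinates as `rowRanges`), columns of the `"counts"`
#' assay are motif panels (one pooled column per panel plus, for
#' multi-pattern panels, one `panel.pattern` column per member pattern).
#' The panel definitions used are carried in `metadata(x)$panels`.
#'
#' @seealso [profileRegions()], [panelCounts()]
#' @exportClass MotifProfile
setClass("MotifProfile", contains = "RangedSummarizedExperiment")

setValidity("MotifProfile", function(object) {
    msg <- character(0)
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is required")
    m <- SummarizedExperiment::assay(object, "counts")
    if (any(!is.finite(m)) || any(m < 0) || any(m != floor(m)))
        msg <- c(msg, "counts must be non-negative integers")
    panels <- S4Vectors::metadata(object)$panels
    for (p in panels) {
        if (!is(p, "MotifPanel")) {
            msg <- c(msg, "metadata(x)$panels must hold MotifPanel objects")
            break
        }
        if (length(p@patterns) > 1L) {
            sub <- paste0(p@name, ".", as.character(p@patterns))
            if (all(sub %in% colnames(m)) && p@name %in% colnames(m)) {
                pooled <- m[, p@name]
                parts <- rowSums(m[, sub, drop = FALSE])
                if (any(pooled != parts))
                    msg <- c(msg, sprintf(
                        "pooled '%s' counts do not equal the sum of per-pattern counts",
                        p@name))
            }
        }
    }
    if (length(msg)) msg else TRUE
})

#' EnrichmentResult: fold enrichment of a panel in ChIP regions vs baseline
#'
#' @slot panel panel name.
#' @slot meanChip,meanBaseline mean motif count per region in each set.
#' @slot fold ratio `meanChip / meanBaseline`.
#' @slot nChip,nBaseline number of regions in each set.
#' @slot ci optional bootstrap percentile interval for the fold (length 0 or 2).
#' @seealso [foldEnrichment()]
#' @exportClass EnrichmentResult
setClass("EnrichmentResult",
    representation(panel = "character", meanChip = "numeric",
                   meanBaseline = "numeric", fold = "numeric",
                   nChip = "integer", nBaseline = "integer", ci = "numeric"))

setValidity("EnrichmentResult", function(object) {
    msg <- character(0)
    if (length(object@panel) != 1L) msg <- c(msg, "'panel' must be length 1")
    if (!length(object@ci) %in% c(0L, 2L))
        msg <- c(msg, "'ci' must have length 0 or 2")
    if (length(object@meanBaseline) == 1L && object@meanBaseline <= 0)
        msg <- c(msg, "fold enrichment is only defined for baseline mean > 0")
    if (length(msg)) msg else TRUE
})

#' ClusterDistribution: how many regions carry 0, 1, 2, >= t panel motifs
#'
#' @slot panel panel name.
#' @slot threshold the clustering cutoff t (default analyses use 3).
#' @slot tallies integer region counts for 0, 1, ..., t-1 and >= t motifs.
#' @slot fractions the tallies divided by the total number of regions.
#' @slot n total number of regions.
#' @seealso [clusterDistribution()]
#' @exportClass ClusterDistribution
setClass("ClusterDistribution",
    representation(panel = "character", threshold = "integer",
                   tallies = "integer", fractions = "numeric", n = "integer"))

setValidity("ClusterDistribution", function(object) {
    msg <- character(0)
    t <- object@threshold
    if (length(t) != 1L || t < 1L) msg <- c(msg, "'threshold' must be >= 1")
    if (length(object@tallies) != t + 1L)
        msg <- c(msg, "'tallies' must have threshold + 1 bins")
    if (length(object@fractions) != length(object@tallies))
        msg <- c(msg, "'fractions' and 'tallies' must align")
    if (object@n > 0L) {
        if (abs(sum(object@fractions) - 1) > 1e-9)
            msg <- c(msg, "fractions must sum to 1")
        if (any(abs(object@fractions - object@tallies / object@n) > 1e-9))
            msg <- c(msg, "fractions must reproduce from tallies / n")
    }
    if (sum(object@tallies) != object@n)
        msg <- c(msg, "tallies must sum to n")
    if (length(msg)) msg else TRUE
})

#' SyntheticSpec: parameters of the synthetic dataset generator
#'
#' Describes a self-contained synthetic study: an i.i.d. background genome
#' with a given GC fraction, non-overlapping "bound" regions carrying planted
#' 5GC-panel motifs, ChIP-like peaks jittered around those regions, and TSS
#' records placing a configurable fraction of bound regions within the
#' promoter-proximal window upstream of a TSS.
#'
#' @slot chromLengths named numeric, chromosome name to length in bp.
#' @slot gcFraction background GC fraction g; P(G)=P(C)=g/2.
#' @slot nBoundRegions number of bound regions to place.
#' @slot regionWidth width of each bound region (bp).
#' @slot plantRate number of motifs planted per bound region: the fixed
#'   count when `plantDistribution = "fixed"`, the Poisson mean otherwise.
#' @slot plantDistribution `"fixed"` or `"poisson"`.
#' @slot motifWeights named probabilities over the planted patterns; must sum to 1.
#' @slot plantStrandProb probability a planted motif goes on the minus strand.
#' @slot peakJitterSd SD (bp) of the Normal displacement of peak centers.
#' @slot promoterFraction fraction of bound regions given an upstream TSS.
#' @slot tssUpstream maximum TSS-to-region-center distance used when placing
#'   TSS records (bp).
#' @slot seed integer seed; every random draw of the generator flows from it.
#' @seealso [syntheticSpec()], [generateGenome()], [emitAnnotation()]
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
    representation(chromLengths = "numeric", gcFraction = "numeric",
                   nBoundRegions = "numeric", regionWidth = "numeric",
                   plantRate = "numeric", plantDistribution = "character",
                   motifWeights = "numeric", plantStrandProb = "numeric",
                   peakJitterSd = "numeric", promoterFraction = "numeric",
                   tssUpstream = "numeric", seed = "numeric"))

setValidity("SyntheticSpec", function(object) {
    msg <- character(0)
    cl <- object@chromLengths
    if (length(cl) < 1L || is.null(names(cl)) || any(!nzchar(names(cl))))
        msg <- c(msg, "'chromLengths' must be a named vector of lengths")
    if (any(cl < 1) || any(cl != floor(cl)))
        msg <- c(msg, "'chromLengths' must be positive integers")
    if (anyDuplicated(names(cl)))
        msg <- c(msg, "'chromLengths' names must be unique")
    .frac <- function(x, what) {
        if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
            sprintf("'%s' must be a single value in [0, 1]", what)
        else character(0)
    }
    msg <- c(msg, .frac(object@gcFraction, "gcFraction"),
                  .frac(object@plantStrandProb, "plantStrandProb"),
                  .frac(object@promoterFraction, "promoterFraction"))
    if (object@nBoundRegions < 0 || object@nBoundRegions != floor(object@nBoundRegions))
        msg <- c(msg, "'nBoundRegions' must be a non-negative integer")
    if (object@regionWidth < 1 || object@regionWidth != floor(object@regionWidth))
        msg <- c(msg, "'regionWidth' must be a positive integer")
    if (object@plantRate < 0)
        msg <- c(msg, "'plantRate' must be non-negative")
    if (!object@plantDistribution %in% c("fixed", "poisson"))
        msg <- c(msg, "'plantDistribution' must be 'fixed' or 'poisson'")
    if (object@plantDistribution == "fixed" &&
        object@plantRate != floor(object@plantRate))
        msg <- c(msg, "fixed 'plantRate' must be an integer count")
    w <- object@motifWeights
    if (length(w) < 1L || is.null(names(w)))
        msg <- c(msg, "'motifWeights' must be a named probability vector")
    else {
        if (abs(sum(w) - 1) > 1e-9)
            msg <- c(msg, "'motifWeights' must sum to 1")
        if (any(w < 0)) msg <- c(msg, "'motifWeights' must be non-negative")
        if (length(unique(nchar(names(w)))) > 1L)
            msg <- c(msg, "planted patterns must share one length")
        chars <- unique(unlist(strsplit(names(w), "")))
        if (!all(chars %in% c("A", "C", "G", "T")))
            msg <- c(msg, "planted patterns must be literal A/C/G/T")
    }
    if (object@peakJitterSd < 0)
        msg <- c(msg, "'peakJitterSd' must be >= 0")
    if (object@tssUpstream < 0)
        msg <- c(msg, "'tssUpstream' must be >= 0")
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "'seed' is required")
    if (length(msg)) msg else TRUE
})
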