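#' @importFrom GenomicRanges GRanges seqnames strand start end width mcols
#'   mcols<- findOverlaps countOverlaps granges resize
#' @importFrom IRanges IRanges subsetByOverlaps
#' @importFrom S4Vectors DataFrame metadata metadata<- subjectHits queryHits
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqlevels
NULL

.complementBase <- function(b) chartr("ACGT", "TGCA", b)

# Apply the 5'-context rule to match start positions on one sequence.
# On "+" the base at start-1 must differ from `notBase`; on "-" the forward
# base just 3' of the footprint must differ from complement(notBase).
# A sequence edge always satisfies the rule.
.contextOK <- function(seqChar, starts, k, strand, notBase) {
    if (is.na(notBase) || length(starts) == 0L)
        return(rep(TRUE, length(starts)))
    if (strand == "+") {
        prev <- substring(seqChar, starts - 1L, starts - 1L)
        starts == 1L | prev != notBase
    } else {
        L <- nchar(seqChar)
        ends <- starts + k - 1L
        nxt <- substring(seqChar, ends + 1L, ends + 1L)
        ends == L | nxt != .complementBase(notBase)
    }
}

#' Scan sequence for motif panel occurrences
#'
#' Exact, strand-aware IUPAC scanning. Every occurrence of every panel
#' pattern is reported (overlapping occurrences included). Minus-strand
#' occurrences are located by matching the reverse complement of the pattern
#' on the forward sequence; their footprint is reported in forward
#' coordinates with `strand = "-"`. `N` in the sequence never matches a
#' literal pattern base. Matching is case-insensitive; with
#' `excludeMasked = TRUE`, hits overlapping soft-masked (lowercase) positions
#' are dropped.
#'
#' @param subject a character vector, [Biostrings::DNAString] or
#'   [Biostrings::DNAStringSet]; each element is scanned independently.
#' @param panel a [MotifPanel-class], or the name of a built-in panel.
#' @param strands `"both"` (default), `"+"` or `"-"`.
#' @param excludeMasked drop hits overlapping lowercase positions.
#' @return a [GenomicRanges::GRanges] of hits (1-based, closed footprints on
#'   the forward coordinate system) sorted by start, strand, pattern, with
#'   metadata columns `pattern` (IUPAC string matched), `panel`, and
#'   `matched` (forward-strand substring of the footprint).
#' @examples
#' scanMotifs("GCGCCGGGGC", builtinPanel("FIVE_GC"))
#' scanMotifs("GTCTAGAC", "AGAC")
#' @export
scanMotifs <- function(subject, panel, strands = c("both", "+", "-"),
                       excludeMasked = FALSE) {
    strands <- match.arg(strands)
    if (is.character(panel)) panel <- builtinPanel(panel)
    stopifnot(is(panel, "MotifPanel"))
    validObject(panel)

    chars <- .asCharSeqs(subject)
    want <- if (strands == "both") c("+", "-") else strands
    k <- patternWidth(panel)
    notBase <- contextRule(panel)

    res <- vector("list", length(chars))
    for (si in seq_along(chars)) {
        raw <- chars[[si]]
        up <- toupper(raw)
        L <- nchar(up)
        dna <- Biostrings::DNAString(if (L) up else "")
        starts <- integer(0); str <- character(0); pat <- character(0)
        for (p in as.character(panelPatterns(panel))) {
            for (sd in want) {
                query <- if (sd == "+") p else revCompIupac(p)
                if (L < k) next
                m <- Biostrings::matchPattern(query, dna, fixed = "subject")
                st <- BiocGenerics::start(m)
                st <- st[.contextOK(up, st, k, sd, notBase)]
                starts <- c(starts, st)
                str <- c(str, rep(sd, length(st)))
                pat <- c(pat, rep(p, length(st)))
            }
        }
        if (excludeMasked && length(starts)) {
            lowPos <- which(strsplit(raw, "")[[1]] %in% letters)
            if (length(lowPos)) {
                hitR <- IRanges(starts, width = k)
                bad <- countOverlaps(hitR, IRanges(lowPos, width = 1L)) > 0L
                starts <- starts[!bad]; str <- str[!bad]; pat <- pat[!bad]
            }
        }
        o <- order(starts, factor(str, levels = c("+", "-")), pat)
        res[[si]] <- GRanges(
            seqnames = rep(names(chars)[si], length(o)),
            ranges = IRanges(starts[o], width = k),
            strand = str[o],
            pattern = pat[o],
            panel = rep(panelName(panel), length(o)),
            matched = if (length(o)) substring(up, starts[o], starts[o] + k - 1L)
                      else character(0))
    }
    hits <- do.call(c, res)
    GenomeInfoDb::seqlevels(hits) <- names(chars)
    GenomeInfoDb::seqlengths(hits) <- vapply(chars, nchar, 1L)
    hits
}

# reverse complement preserving IUPAC ambiguity codes
revCompIupac <- function(p)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(p)))

# Normalise subject input into a named list of character sequences.
.asCharSeqs <- function(subject) {
    if (is(subject, "DNAString"))
        subject <- Biostrings::DNAStringSet(subject)
    if (is(subject, "DNAStringSet")) {
        out <- as.list(as.character(subject))
    } else if (is.character(subject)) {
        out <- as.list(subject)
    } else stop("'subject' must be character, DNAString or DNAStringSet")
    if (is.null(names(out)) || any(!nzchar(names(out))))
        names(out) <- if (length(out) == 1L) "seq"
                      else sprintf("seq%d", seq_along(out))
    out
}

#' Count hits fully contained in regions
#'
#' A hit is counted for a region only when its footprint lies entirely
#' within the region (strand ignored).
#'
#' @param hits `GRanges` of motif hits (e.g. from [scanMotifs()]).
#' @param regions `GRanges` of regions in the same coordinate system.
#' @return integer vector, one count per region.
#' @export
countHitsInRegion <- function(hits, regions) {
    stopifnot(is(hits, "GRanges"), is(regions, "GRanges"))
    ov <- findOverlaps(hits, regions, type = "within", ignore.strand = TRUE)
    tabulate(subjectHits(ov), nbins = length(regions))
}
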