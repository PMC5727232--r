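# Independent oracles: a character-level brute-force scanner that tests
# every offset/strand/pattern combination one by one, and an exhaustive
# include/exclude search for the footprint-capacity problem. Deliberately
# share no code with the package internals.

ORACLE_IUPAC <- c(A = "A", C = "C", G = "G", T = "T",
                  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

oracleExpand <- function(pat) {
    sets <- lapply(strsplit(pat, "")[[1]],
                   function(l) strsplit(ORACLE_IUPAC[[l]], "")[[1]])
    Reduce(function(a, b) as.vector(outer(a, b, paste0)), sets, "")
}

oracleRevComp <- function(s)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")

# data.frame(start, strand, pattern) of all occurrences, 1-based closed,
# sorted like the scanner output (start, then + before -, then pattern)
bruteScan <- function(seq, patterns, strands = "both",
                      fivePrimeNot = NA_character_) {
    seq <- toupper(seq)
    L <- nchar(seq)
    want <- if (strands == "both") c("+", "-") else strands
    rows <- list()
    for (p in patterns) {
        k <- nchar(p)
        if (L < k) next
        fwdSet <- oracleExpand(p)
        revSet <- vapply(fwdSet, oracleRevComp, "", USE.NAMES = FALSE)
        for (i in seq_len(L - k + 1L)) {
            sub <- substr(seq, i, i + k - 1L)
            if ("+" %in% want && sub %in% fwdSet) {
                ok <- is.na(fivePrimeNot) || i == 1L ||
                    substr(seq, i - 1L, i - 1L) != fivePrimeNot
                if (ok) rows[[length(rows) + 1L]] <- list(i, "+", p)
            }
            if ("-" %in% want && sub %in% revSet) {
                j <- i + k
                ok <- is.na(fivePrimeNot) || j > L ||
                    substr(seq, j, j) != chartr("ACGT", "TGCA", fivePrimeNot)
                if (ok) rows[[length(rows) + 1L]] <- list(i, "-", p)
            }
        }
    }
    if (!length(rows))
        return(data.frame(start = integer(), strand = character(),
                          pattern = character(), stringsAsFactors = FALSE))
    d <- data.frame(start = vapply(rows, `[[`, 1L, 1),
                    strand = vapply(rows, `[[`, "", 2),
                    pattern = vapply(rows, `[[`, "", 3),
                    stringsAsFactors = FALSE)
    d <- d[order(d$start, match(d$strand, c("+", "-")), d$pattern), , drop = FALSE]
    rownames(d) <- NULL
    d
}

hitsAsDf <- function(hits) {
    d <- data.frame(start = GenomicRanges::start(hits),
                    strand = as.character(GenomicRanges::strand(hits)),
                    pattern = hits$pattern, stringsAsFactors = FALSE)
    rownames(d) <- NULL
    d
}

# exhaustive include/exclude search over hit subsets
bruteCapacity <- function(starts, footprint) {
    if (!length(starts)) return(0L)
    s <- sort(starts)
    rec <- function(i, minStart) {
        if (i > length(s)) return(0L)
        best <- rec(i + 1L, minStart)
        if (s[i] >= minStart)
            best <- max(best, 1L + rec(i + 1L, s[i] + footprint))
        best
    }
    rec(1L, -Inf)
}

randDNA <- function(L, gc = 0.5) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
}

# build a MotifProfile with prescribed counts for hand-arithmetic tests
profileFromCounts <- function(counts, panel = "AGAC") {
    mat <- matrix(as.integer(counts), ncol = 1,
                  dimnames = list(NULL, panel))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = mat),
        rowRanges = GenomicRanges::GRanges(
            sprintf("r%d", seq_along(counts)),
            IRanges::IRanges(1, 200)),
        metadata = list(panels = list(builtinPanel(panel)), strands = "both"))
    new("MotifProfile", se)
}

ALL_PANELS <- c("FIVE_GC", "CONSENSUS_5GC", "CAGAC", "AGAC", "DAGAC", "GTCT")
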