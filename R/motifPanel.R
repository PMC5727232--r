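#' Construct a motif panel
#'
#' @param name panel label.
#' @param patterns character vector or [Biostrings::DNAStringSet] of
#'   equal-length IUPAC patterns. Consensus notation with one alternation
#'   group (e.g. `"GGC(GC|CG)"`) is expanded via [expandConsensus()].
#' @param fivePrimeNot `NA` (default) or a single base: a match only counts
#'   when the base immediately 5' of it on the match's strand differs from
#'   this base; a sequence edge satisfies the rule.
#' @return a [MotifPanel-class] object.
#' @examples
#' motifPanel("FIVE_GC", c("GGCGC", "GGCGG", "GGCCG", "GGCTG"))
#' motifPanel("DAGAC", "AGAC", fivePrimeNot = "C")
#' @export
motifPanel <- function(name, patterns, fivePrimeNot = NA_character_) {
    if (is.character(patterns)) {
        patterns <- toupper(patterns)
        if (any(grepl("[(|)]", patterns)))
            patterns <- unique(unlist(lapply(patterns, expandConsensus)))
        patterns <- Biostrings::DNAStringSet(patterns)
    }
    if (is.null(names(patterns)) || any(!nzchar(names(patterns))))
        names(patterns) <- as.character(patterns)
    new("MotifPanel", name = name, patterns = patterns,
        fivePrimeNot = if (is.na(fivePrimeNot)) NA_character_
                       else toupper(fivePrimeNot))
}

#' Built-in motif panels
#'
#' `builtinPanel()` returns one of the panels used throughout the analyses;
#' `builtinPanels()` returns the default set used for region profiling.
#'
#' * `FIVE_GC` — the GC-rich 5-bp Smad binding elements
#'   GGCGC, GGCGG, GGCCG, GGCTG (the 5GC SBE panel).
#' * `CONSENSUS_5GC` — the consensus `GGC(GC|CG)` expanded: GGCGC, GGCCG.
#' * `CAGAC` — the classical Smad binding element.
#' * `AGAC` — the 4-bp core.
#' * `DAGAC` — AGAC whose immediately 5' base is not C
#'   (IUPAC D = A/G/T), i.e. AGAC occurrences outside CAGAC.
#' * `GTCT` — the reverse complement of AGAC, as a forward pattern.
#'
#' @param name one of `"FIVE_GC"`, `"CONSENSUS_5GC"`, `"CAGAC"`, `"AGAC"`,
#'   `"DAGAC"`, `"GTCT"`.
#' @return a [MotifPanel-class] (`builtinPanel`) or named list of panels
#'   (`builtinPanels`).
#' @examples
#' builtinPanel("FIVE_GC")
#' names(builtinPanels())
#' @export
builtinPanel <- function(name = c("FIVE_GC", "CONSENSUS_5GC", "CAGAC",
                                  "AGAC", "DAGAC", "GTCT")) {
    name <- match.arg(name)
    switch(name,
        FIVE_GC = motifPanel("FIVE_GC", c("GGCGC", "GGCGG", "GGCCG", "GGCTG")),
        CONSENSUS_5GC = motifPanel("CONSENSUS_5GC", expandConsensus("GGC(GC|CG)")),
        CAGAC = motifPanel("CAGAC", "CAGAC"),
        AGAC = motifPanel("AGAC", "AGAC"),
        DAGAC = motifPanel("DAGAC", "AGAC", fivePrimeNot = "C"),
        GTCT = motifPanel("GTCT", "GTCT"))
}

#' @rdname builtinPanel
#' @export
builtinPanels <- function() {
    nm <- c("FIVE_GC", "CAGAC", "AGAC", "DAGAC")
    stats::setNames(lapply(nm, builtinPanel), nm)
}

#' Read motif panels from a YAML config
#'
#' Each entry must carry `name` and `patterns` (list of IUPAC strings) and
#' may carry `five_prime_not`.
#'
#' @param path a YAML file.
#' @return named list of [MotifPanel-class] objects.
#' @export
readPanelConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    panels <- lapply(cfg, function(e) {
        motifPanel(e$name, unlist(e$patterns),
                   fivePrimeNot = if (is.null(e$five_prime_not))
                       NA_character_ else e$five_prime_not)
    })
    stats::setNames(panels, vapply(panels, panelName, ""))
}

#' @rdname MotifPanel-class
#' @export
setMethod("panelName", "MotifPanel", function(x) x@name)

#' @rdname MotifPanel-class
#' @export
setMethod("panelPatterns", "MotifPanel", function(x) x@patterns)

#' @rdname MotifPanel-class
#' @export
setMethod("patternWidth", "MotifPanel",
    function(x) unique(Biostrings::width(x@patterns)))

#' @rdname MotifPanel-class
#' @export
setMethod("contextRule", "MotifPanel", function(x) x@fivePrimeNot)

setMethod("show", "MotifPanel", function(object) {
    cat("MotifPanel '", object@name, "': ",
        paste(as.character(object@patterns), collapse = ", "), sep = "")
    if (!is.na(object@fivePrimeNot))
        cat(" [5' base != ", object@fivePrimeNot, "]", sep = "")
    cat(" (width ", patternWidth(object), ")\n", sep = "")
})

#' Reverse complement of a DNA string
#'
#' Thin character-level wrapper around
#' [Biostrings::reverseComplement()] that accepts A/C/G/T/N
#' (case-insensitive) and returns uppercase.
#'
#' @param seq character vector of DNA strings.
#' @return character vector of reverse complements, same length.
#' @examples
#' revComp("GGCGC")     # "GCGCC"
#' revComp("GTCTAGAC")  # palindromic duplex: returns itself
#' @export
revComp <- function(seq) {
    stopifnot(is.character(seq))
    vapply(seq, function(s) {
        s <- toupper(s)
        if (nchar(s) == 0L) return("")
        if (grepl("[^ACGTN]", s))
            stop("non-nucleotide character in '", s,
                 "': only A/C/G/T/N are accepted")
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }, character(1), USE.NAMES = FALSE)
}

#' Expand consensus notation into concrete patterns
#'
#' Accepts literal bases, IUPAC ambiguity codes, and alternation groups
#' written `(XY|ZW)` (the variant spelling `(XY)|(ZW)` is normalised first).
#' Every combination of group branches and ambiguity expansions is returned.
#'
#' @param notation a single consensus string, e.g. `"GGC(GC|CG)"`.
#' @return character vector of concrete A/C/G/T patterns.
#' @examples
#' expandConsensus("GGC(GC|CG)")  # GGCGC, GGCCG
#' expandConsensus("DAGAC")       # AAGAC, GAGAC, TAGAC
#' @export
expandConsensus <- function(notation) {
    stopifnot(is.character(notation), length(notation) == 1L)
    x <- toupper(gsub(")|(", "|", notation, fixed = TRUE))
    letter <- paste0("[", paste(.IUPAC_LETTERS, collapse = ""), "]")
    tokenRe <- paste0("\\((?:", letter, "+\\|)+", letter, "+\\)|", letter)
    toks <- regmatches(x, gregexpr(tokenRe, x, perl = TRUE))[[1]]
    if (paste(toks, collapse = "") != x)
        stop("malformed consensus notation: '", notation, "'")
    map <- Biostrings::IUPAC_CODE_MAP
    expandLiteral <- function(s) {
        # cartesian product of per-letter base sets
        sets <- lapply(strsplit(s, "")[[1]], function(l) strsplit(map[[l]], "")[[1]])
        Reduce(function(a, b) as.vector(outer(a, b, paste0)), sets, "")
    }
    out <- ""
    for (tk in toks) {
        alts <- if (startsWith(tk, "(")) {
            branches <- strsplit(substr(tk, 2L, nchar(tk) - 1L), "|", fixed = TRUE)[[1]]
            if (any(!nzchar(branches)))
                stop("malformed consensus notation: empty branch in '", notation, "'")
            unlist(lapply(branches, expandLiteral))
        } else expandLiteral(tk)
        out <- as.vector(t(outer(out, alts, paste0)))
    }
    unique(out)
}
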