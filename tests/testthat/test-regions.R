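# Region construction: windows, promoter filter, exclusion, baseline
# sampling, sequence extraction, and the interval-format readers.

library(GenomicRanges)

test_that("centerWindows centers, drops edge windows, and deduplicates", {
    sizes <- c(chr1 = 10000)
    # peak 1001-1300 (1-based closed): midpoint 1150 (0-based), window 1051-1250
    w <- centerWindows(GRanges("chr1", IRanges(1001, 1300)), chromSizes = sizes)
    expect_identical(start(w), 1051L)
    expect_identical(end(w), 1250L)
    expect_identical(width(w), 200L)
    expect_identical(S4Vectors::metadata(w)$provenance, "chip")

    # a peak too close to the chromosome start is dropped, not clipped
    near <- GRanges("chr1", IRanges(1, 50))
    expect_identical(length(centerWindows(near, chromSizes = sizes)), 0L)
    # and too close to the end
    far <- GRanges("chr1", IRanges(9951, 10000))
    expect_identical(length(centerWindows(far, chromSizes = sizes)), 0L)

    # duplicate peaks give one distinct window
    dup <- GRanges("chr1", IRanges(c(1001, 1001, 2001), c(1300, 1300, 2300)))
    expect_identical(length(centerWindows(dup, chromSizes = sizes)), 2L)

    expect_error(centerWindows(GRanges("chr1", IRanges(1001, 1300)),
                               width = 201, chromSizes = sizes), "even")
    expect_error(centerWindows(GRanges("chrX", IRanges(1001, 1300)),
                               chromSizes = sizes), "chrX")
})

test_that("centerWindows honours narrowPeak summits only when asked", {
    sizes <- c(chr1 = 10000)
    pk <- GRanges("chr1", IRanges(1001, 1300), summit = 10L)
    expect_identical(start(centerWindows(pk, chromSizes = sizes)), 1051L)
    # summit: center0 = 1000 + 10 = 1010 -> window 911-1110
    ws <- centerWindows(pk, useSummit = TRUE, chromSizes = sizes)
    expect_identical(start(ws), 911L)
    expect_identical(end(ws), 1110L)
    # absent summit falls back to the midpoint
    pk2 <- GRanges("chr1", IRanges(1001, 1300), summit = NA_integer_)
    expect_identical(start(centerWindows(pk2, useSummit = TRUE,
                                         chromSizes = sizes)), 1051L)
})

test_that("promoterFilter keeps regions upstream of a TSS, strand-aware", {
    # + strand TSS at 0-based position 5000
    tssP <- GRanges("chr1", IRanges(5001, 5001), strand = "+")
    # region centered 600 bp upstream (center0 = 4400): 4301-4500
    r600 <- GRanges("chr1", IRanges(4301, 4500))
    expect_identical(length(promoterFilter(r600, tssP)), 1L)
    # 1100 bp upstream: dropped
    r1100 <- GRanges("chr1", IRanges(3801, 4000))
    expect_identical(length(promoterFilter(r1100, tssP)), 0L)
    # exactly at the TSS: kept (inclusive window)
    r0 <- GRanges("chr1", IRanges(4901, 5100))
    expect_identical(length(promoterFilter(r0, tssP)), 1L)
    # downstream of a + TSS: dropped in upstream_only, kept in symmetric
    rDown <- GRanges("chr1", IRanges(5501, 5700))
    expect_identical(length(promoterFilter(rDown, tssP)), 0L)
    expect_identical(length(promoterFilter(rDown, tssP, mode = "symmetric")), 1L)

    # - strand TSS at p: center at p + 600 is upstream, kept
    tssM <- GRanges("chr1", IRanges(5001, 5001), strand = "-")
    rUpM <- GRanges("chr1", IRanges(5501, 5700))
    expect_identical(length(promoterFilter(rUpM, tssM)), 1L)
    rDownM <- GRanges("chr1", IRanges(4301, 4500))
    expect_identical(length(promoterFilter(rDownM, tssM)), 0L)

    expect_error(promoterFilter(r600, GRanges()), "empty TSS")
    expect_error(promoterFilter(r600, GRanges("chr1", IRanges(5001, 5001))),
                 "strand")
})

test_that("symmetric promoter mode is a superset of upstream-only", {
    set.seed(91)
    for (i in 1:15) {
        regions <- GRanges("chr1",
            IRanges(sample(1:20000, 40) * 10 + 1, width = 200))
        tss <- GRanges("chr1", IRanges(sample(1:200000, 5), width = 1),
                       strand = sample(c("+", "-"), 5, TRUE))
        up <- promoterFilter(regions, tss)
        sym <- promoterFilter(regions, tss, mode = "symmetric")
        expect_true(all(paste(start(up)) %in% paste(start(sym))))
    }
})

test_that("excludeOverlapping removes 1-bp overlaps, keeps abutments, is monotone", {
    regions <- GRanges("chr1", IRanges(101, 300))
    expect_identical(length(excludeOverlapping(
        regions, GRanges("chr1", IRanges(300, 400)))), 0L)  # shares bp 300
    expect_identical(length(excludeOverlapping(
        regions, GRanges("chr1", IRanges(301, 400)))), 1L)  # abutment
    expect_identical(length(excludeOverlapping(regions, GRanges())), 1L)

    set.seed(7)
    regions <- GRanges("chr1", IRanges(sample(1:5000, 50) * 3, width = 200))
    othersA <- GRanges("chr1", IRanges(sample(1:15000, 10), width = 300))
    othersB <- c(othersA, GRanges("chr1", IRanges(sample(1:15000, 10), width = 300)))
    keptA <- excludeOverlapping(regions, othersA)
    keptB <- excludeOverlapping(regions, othersB)
    expect_true(length(keptB) <= length(keptA))
    expect_true(all(start(keptB) %in% start(keptA)))
})

test_that("sampleBaseline is deterministic, in-bounds, and exact in n and width", {
    set.seed(1)
    genome <- Biostrings::DNAStringSet(c(chrA = randDNA(3000), chrB = randDNA(2000)))
    b1 <- sampleBaseline(genome, n = 100, width = 200, seed = 42)
    b2 <- sampleBaseline(genome, n = 100, width = 200, seed = 42)
    expect_identical(as.data.frame(b1), as.data.frame(b2))
    b3 <- sampleBaseline(genome, n = 100, width = 200, seed = 43)
    expect_false(identical(as.data.frame(b1), as.data.frame(b3)))

    expect_identical(length(b1), 100L)
    expect_true(all(width(b1) == 200L))
    lens <- c(chrA = 3000L, chrB = 2000L)
    expect_true(all(start(b1) >= 1L))
    expect_true(all(end(b1) <= lens[as.character(seqnames(b1))]))
    expect_identical(S4Vectors::metadata(b1)$provenance, "baseline")

    expect_error(sampleBaseline(genome, n = 10, width = 200), "seed")
    short <- Biostrings::DNAStringSet(c(c1 = randDNA(150)))
    expect_error(sampleBaseline(short, n = 5, width = 200, seed = 1),
                 "at least")
})

test_that("sampleBaseline rejects N-rich draws", {
    set.seed(2)
    genome <- Biostrings::DNAStringSet(
        c(chrA = randDNA(2000), chrN = strrep("N", 2000)))
    b <- sampleBaseline(genome, n = 50, width = 200, seed = 9,
                        maxNFraction = 0.1)
    expect_true(all(as.character(seqnames(b)) == "chrA"))
    # with no usable sequence, sampling fails with a diagnostic
    allN <- Biostrings::DNAStringSet(c(chrN = strrep("N", 2000)))
    expect_error(sampleBaseline(allN, n = 5, width = 200, seed = 9),
                 "redraw")
})

test_that("baseline starts are uniform over a two-chromosome toy genome", {
    genome <- Biostrings::DNAStringSet(
        c(chrA = strrep("A", 3000), chrB = strrep("A", 2000)))
    b <- sampleBaseline(genome, n = 20000, width = 200, seed = 77)
    # valid starts: 2801 on chrA, 1801 on chrB; bin each chromosome into 10
    valid <- c(chrA = 2801, chrB = 1801)
    counts <- integer(0)
    probs <- numeric(0)
    for (chr in names(valid)) {
        st <- start(b)[as.character(seqnames(b)) == chr]
        bins <- cut(st, breaks = seq(1, valid[chr] + 1, length.out = 11),
                    right = FALSE)
        counts <- c(counts, as.integer(table(bins)))
        probs <- c(probs, rep(valid[chr] / 10, 10))
    }
    p <- stats::chisq.test(counts, p = probs / sum(probs))$p.value
    expect_gt(p, 0.01)
})

test_that("extractSequences round-trips through FASTA and validates bounds", {
    set.seed(3)
    genome <- Biostrings::DNAStringSet(
        c(chrA = paste0("GCGCC", randDNA(995)), chrB = randDNA(500)))
    regions <- GRanges(c("chrA", "chrA", "chrB"),
                       IRanges(c(1, 101, 51), width = c(5, 200, 200)))
    seqs <- extractSequences(genome, regions)
    expect_identical(as.character(seqs[[1]]), "GCGCC")
    expect_identical(Biostrings::width(seqs), c(5L, 200L, 200L))

    # on-disk FASTA path gives the same sequences
    fa <- file.path(withr::local_tempdir(), "g.fa")
    Biostrings::writeXStringSet(genome, fa)
    seqs2 <- extractSequences(fa, regions)
    expect_identical(as.character(seqs), as.character(seqs2))

    oob <- GRanges("chrB", IRanges(450, 649))
    expect_error(extractSequences(genome, oob), "chrB:450-649")
    expect_error(extractSequences(genome, GRanges("chrZ", IRanges(1, 10))),
                 "chrZ")
})

test_that("peak, TSS and chrom.sizes readers parse the standard formats", {
    dir <- withr::local_tempdir()
    bed <- file.path(dir, "peaks.bed")
    writeLines(c("chrA\t100\t300\tpk1\t5\t+", "chrA\t500\t900\tpk2\t7\t-"), bed)
    pk <- readPeaks(bed)
    expect_identical(start(pk), c(101L, 501L))  # BED 0-based -> 1-based
    expect_identical(end(pk), c(300L, 900L))
    expect_true(all(is.na(pk$summit)))

    np <- file.path(dir, "peaks.narrowPeak")
    writeLines(c("chrA\t100\t300\tpk1\t0\t.\t5.5\t4.4\t3.3\t25",
                 "chrA\t500\t900\tpk2\t0\t.\t5.5\t4.4\t3.3\t-1"), np)
    pk2 <- readPeaks(np)
    expect_identical(pk2$summit, c(25L, NA_integer_))

    tssBed <- file.path(dir, "tss.bed")
    writeLines(c("chrA\t1000\t1200\tgeneA\t0\t+",
                 "chrA\t2000\t2200\tgeneB\t0\t-"), tssBed)
    tss <- readTSS(tssBed)
    expect_identical(width(tss), c(1L, 1L))
    expect_identical(start(tss), c(1001L, 2200L))  # 5' end on each strand
    expect_identical(tss$gene_id, c("geneA", "geneB"))

    gtf <- file.path(dir, "tx.gtf")
    writeLines(c(
        paste0("chrA\tsrc\ttranscript\t1001\t1200\t.\t+\t.\t",
               'gene_id "gA"; transcript_id "tA";'),
        paste0("chrA\tsrc\texon\t1001\t1100\t.\t+\t.\t",
               'gene_id "gA"; transcript_id "tA";'),
        paste0("chrA\tsrc\ttranscript\t2001\t2200\t.\t-\t.\t",
               'gene_id "gB"; transcript_id "tB";')), gtf)
    tss2 <- readTSS(gtf)
    expect_identical(length(tss2), 2L)  # exon record ignored
    expect_identical(start(tss2), c(1001L, 2200L))
    expect_identical(tss2$gene_id, c("tA", "tB"))

    cs <- file.path(dir, "c.sizes")
    writeLines(c("chrA\t3000", "chrB\t2000"), cs)
    expect_identical(readChromSizes(cs), c(chrA = 3000, chrB = 2000))

    # BED writer round trip (coordinates preserved through 0-based BED)
    out <- file.path(dir, "regions.bed")
    writeRegionsBed(GRanges("chrA", IRanges(c(101, 501), width = 200)), out)
    back <- rtracklayer::import(out, format = "BED")
    expect_identical(start(back), c(101L, 501L))
})
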