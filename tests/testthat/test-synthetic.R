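# Synthetic dataset generator: determinism, planting guarantees, analytic
# background oracle, annotation emission.

library(GenomicRanges)

smallSpec <- function(...) {
    args <- list(chromLengths = c(cA = 120000, cB = 80000),
                 nBoundRegions = 40, seed = 404)
    dots <- list(...)
    args[names(dots)] <- dots
    do.call(syntheticSpec, args)
}

test_that("invalid generator specs are rejected with named fields", {
    expect_error(smallSpec(gcFraction = 1.2), "gcFraction")
    expect_error(smallSpec(motifWeights = c(GGCGC = 0.5, GGCTG = 0.6)),
                 "sum to 1")
    expect_error(smallSpec(motifWeights = c(0.5, 0.5)), "named")
    expect_error(smallSpec(plantStrandProb = -0.1), "plantStrandProb")
    expect_error(smallSpec(nBoundRegions = -1), "nBoundRegions")
    expect_error(smallSpec(peakJitterSd = -2), "peakJitterSd")
    expect_error(syntheticSpec(chromLengths = c(1000, 2000)), "named")
    # a region too small for the requested plant count fails at generation
    expect_error(generateGenome(smallSpec(regionWidth = 12, plantRate = 3)),
                 "cannot hold")
})

test_that("generation is reproducible under the seed, and seed-sensitive", {
    g1 <- generateGenome(smallSpec())
    g2 <- generateGenome(smallSpec())
    expect_identical(as.character(g1$genome), as.character(g2$genome))
    expect_identical(as.data.frame(g1$truth), as.data.frame(g2$truth))
    g3 <- generateGenome(smallSpec(seed = 405))
    expect_false(identical(as.character(g1$genome), as.character(g3$genome)))
})

test_that("runSimulate writes byte-identical FASTA under one seed", {
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    runSimulate(smallSpec(), d1)
    runSimulate(smallSpec(), d2)
    expect_identical(readLines(file.path(d1, "genome.fa")),
                     readLines(file.path(d2, "genome.fa")))
    for (f in c("genome.fa", "genome.fa.fai", "peaks.bed", "tss.bed",
                "chrom.sizes", "truth.tsv", "spec.yaml"))
        expect_true(file.exists(file.path(d1, f)), info = f)
})

test_that("every planted motif is recovered by the scanner (100% recall)", {
    sim <- generateGenome(smallSpec())
    truth <- sim$truth
    expect_identical(length(truth), 40L * 3L)
    for (chr in names(sim$genome)) {
        tr <- truth[as.character(seqnames(truth)) == chr]
        if (!length(tr)) next
        hits <- scanMotifs(as.character(sim$genome[[chr]]), "FIVE_GC")
        hkey <- paste(start(hits), as.character(strand(hits)), hits$pattern)
        tkey <- paste(start(tr), as.character(strand(tr)), tr$pattern)
        expect_true(all(tkey %in% hkey), info = chr)
    }
})

test_that("bound regions carry their background count plus exactly k plants", {
    sim <- generateGenome(smallSpec())
    counts <- panelCounts(
        profileRegions(extractSequences(sim$genome, sim$bound)), "FIVE_GC")
    # planting adds k on top of a non-negative background count
    expect_true(all(counts >= 3L))
    expect_identical(sim$bound$nPlanted, rep(3L, 40))
    # cluster fraction >= 3 is 1.0 by construction
    prof <- profileRegions(extractSequences(sim$genome, sim$bound))
    d <- clusterDistribution(prof, "FIVE_GC")
    expect_equal(unname(clusterFractions(d)[">=3"]), 1.0)
})

test_that("plant rate zero leaves bound regions as plain background", {
    sim <- generateGenome(smallSpec(plantRate = 0))
    expect_identical(length(sim$truth), 0L)
    expect_identical(sim$bound$nPlanted, rep(0L, 40))
    # and the genome is untouched background: regenerating the same spec
    # with planting gives a genome differing only inside bound regions
    expect_identical(length(sim$bound), 40L)
})

test_that("bound regions are mutually non-overlapping and within bounds", {
    sim <- generateGenome(smallSpec(nBoundRegions = 120))
    b <- sim$bound
    expect_identical(length(b), 120L)
    expect_true(all(width(b) == 200L))
    hits <- findOverlaps(b, drop.self = TRUE)
    expect_identical(length(hits), 0L)
    lens <- c(cA = 120000, cB = 80000)
    expect_true(all(end(b) <= lens[as.character(seqnames(b))]))
})

test_that("poisson plant rates vary per region and are all recoverable", {
    sim <- generateGenome(smallSpec(plantRate = 1.5,
                                    plantDistribution = "poisson"))
    expect_gt(stats::var(sim$bound$nPlanted), 0)
    expect_identical(sum(sim$bound$nPlanted), length(sim$truth))
})

test_that("analytic background expectation matches the closed forms", {
    expect_equal(expectedBackgroundCount("FIVE_GC", 200, 0.5),
                 2 * 196 * 4 / 1024)                      # 1.53125
    expect_equal(expectedBackgroundCount(motifPanel("x", "GGCGC"), 200, 0.5),
                 2 * 196 / 1024)                          # 0.3828125
    expect_equal(expectedBackgroundCount(motifPanel("x", "GGCGC"), 200, 0.6),
                 2 * 196 * 0.3^5, tolerance = 1e-9)       # 0.95256
    # forward-only is exactly half for a symmetric base composition
    expect_equal(expectedBackgroundCount("FIVE_GC", 200, 0.5, strands = "+"),
                 expectedBackgroundCount("FIVE_GC", 200, 0.5) / 2)
    # width shorter than the pattern has zero expectation
    expect_equal(expectedBackgroundCount("FIVE_GC", 4, 0.5), 0)
    # the DAGAC context rule prunes the C-preceded fraction of AGAC
    expect_lt(expectedBackgroundCount("DAGAC", 200, 0.5),
              expectedBackgroundCount("AGAC", 200, 0.5))
    # 196 interior windows carry the not-C factor, the edge window does not
    expect_equal(expectedBackgroundCount("DAGAC", 200, 0.5),
                 2 * (196 * 0.75 + 1) / 256, tolerance = 1e-9)
})

test_that("peaks track bound regions; jitter zero means exact centers", {
    spec <- smallSpec(peakJitterSd = 0)
    sim <- generateGenome(spec)
    ann <- emitAnnotation(spec, sim)
    expect_identical(length(ann$peaks), 40L)
    expect_identical(start(ann$peaks), start(sim$bound))
    expect_identical(end(ann$peaks), end(sim$bound))
    spec2 <- smallSpec(peakJitterSd = 15)
    sim2 <- generateGenome(spec2)
    ann2 <- emitAnnotation(spec2, sim2)
    expect_false(all(start(ann2$peaks) == start(sim2$bound)))
})

test_that("promoterFraction controls how many windows the TSS filter keeps", {
    spec <- smallSpec(peakJitterSd = 0, promoterFraction = 1)
    sim <- generateGenome(spec)
    ann <- emitAnnotation(spec, sim)
    expect_identical(length(ann$tss), 40L)
    wins <- centerWindows(ann$peaks, chromSizes = spec@chromLengths)
    kept <- promoterFilter(wins, ann$tss)
    expect_identical(length(kept), length(wins))  # all retained

    specH <- smallSpec(peakJitterSd = 0, promoterFraction = 0.5)
    simH <- generateGenome(specH)
    annH <- emitAnnotation(specH, simH)
    expect_identical(length(annH$tss), 20L)
    winsH <- centerWindows(annH$peaks, chromSizes = specH@chromLengths)
    keptH <- promoterFilter(winsH, annH$tss)
    # every TSS'd region is kept by construction; a few extra windows may be
    # coincidentally proximal to a neighbouring region's TSS
    tssRegions <- annH$tss$gene_id
    expect_gte(length(keptH), 20L)
    expect_lt(length(keptH), 40L)

    specZ <- smallSpec(promoterFraction = 0)
    annZ <- emitAnnotation(specZ, generateGenome(specZ))
    expect_identical(length(annZ$tss), 0L)
    expect_error(promoterFilter(winsH, annZ$tss), "empty TSS")
})

test_that("an empty study (no bound regions) still yields a valid genome", {
    spec <- smallSpec(nBoundRegions = 0)
    sim <- generateGenome(spec)
    expect_identical(length(sim$bound), 0L)
    expect_identical(length(sim$truth), 0L)
    expect_identical(Biostrings::width(sim$genome), c(120000L, 80000L))
    d <- withr::local_tempdir()
    runSimulate(spec, d)
    expect_true(file.exists(file.path(d, "peaks.bed")))
    expect_identical(length(readLines(file.path(d, "peaks.bed"))), 0L)
})

test_that("spec serialises to YAML and back without loss", {
    spec <- smallSpec(gcFraction = 0.37, plantRate = 2)
    d <- withr::local_tempdir()
    yaml::write_yaml(specAsList(spec), file.path(d, "s.yaml"))
    back <- yaml::read_yaml(file.path(d, "s.yaml"))
    expect_equal(unlist(back$chrom_lengths), c(cA = 120000, cB = 80000))
    expect_equal(back$gc_fraction, 0.37)
    expect_equal(back$plant_rate, 2)
    expect_equal(back$seed, 404)
})
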