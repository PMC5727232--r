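# End-to-end orchestration: read peaks -> center windows -> promoter filter
# -> (optional peak exclusion) -> extract sequences -> profile -> baseline
# -> enrichment / cluster / co-occurrence statistics -> TSV + JSON report.

#' Build a run configuration
#'
#' Every parameter carries the default used throughout the analyses
#' (200-bp windows, 1000-bp promoter window, 500 baseline regions,
#' cluster threshold 3, both strands); all are overridable. The object
#' round-trips through YAML unchanged via [writeRunConfig()] /
#' [readRunConfig()].
#'
#' @param genome path to the genome FASTA.
#' @param peaks path to the ChIP-Seq peak file (BED/narrowPeak).
#' @param tss path to the TSS annotation (BED6 or GFF/GTF).
#' @param excludePeaks character vector of peak files whose overlaps are
#'   removed (e.g. SP1/CTCF peak sets), or `NULL`.
#' @param width analysis window width (bp).
#' @param maxUpstream promoter window size upstream of the TSS (bp).
#' @param baselineN number of random baseline regions.
#' @param clusterThreshold cluster cutoff for the distribution statistics.
#' @param strands `"both"`, `"+"` or `"-"`.
#' @param useSummit center windows on narrowPeak summits where recorded.
#' @param promoterMode `"upstream_only"` or `"symmetric"`.
#' @param seed integer seed (drives baseline sampling).
#' @param outDir output directory for the report bundle.
#' @return a `RunConfig` (validated named list).
#' @export
runConfig <- function(genome, peaks, tss, excludePeaks = NULL,
                      width = 200L, maxUpstream = 1000L, baselineN = 500L,
                      clusterThreshold = 3L, strands = "both",
                      useSummit = FALSE,
                      promoterMode = "upstream_only", seed, outDir) {
    if (missing(seed)) stop("'seed' is required")
    if (missing(outDir)) stop("'outDir' is required")
    cfg <- list(genome = genome, peaks = peaks, tss = tss,
                excludePeaks = excludePeaks, width = as.integer(width),
                maxUpstream = as.integer(maxUpstream),
                baselineN = as.integer(baselineN),
                clusterThreshold = as.integer(clusterThreshold),
                strands = match.arg(strands, c("both", "+", "-")),
                useSummit = isTRUE(useSummit),
                promoterMode = match.arg(promoterMode,
                                         c("upstream_only", "symmetric")),
                seed = as.integer(seed), outDir = outDir)
    class(cfg) <- c("RunConfig", "list")
    cfg
}

#' @rdname runConfig
#' @param config a `RunConfig`.
#' @param path a YAML file path.
#' @export
writeRunConfig <- function(config, path) {
    stopifnot(inherits(config, "RunConfig"))
    yaml::write_yaml(unclass(config), path)
    invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    do.call(runConfig, cfg[!vapply(cfg, is.null, TRUE)])
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

.log <- function(...) message("[SBEscan] ", ...)

#' Run the enrichment pipeline end to end
#'
#' Executes the full analysis described by a [runConfig()]: peak-centered
#' window construction, promoter-proximity filtering, optional exclusion of
#' regions overlapped by other peak sets, sequence extraction, motif
#' profiling of the ChIP windows and of a random genomic baseline, and the
#' enrichment, cluster-distribution and co-occurrence statistics. Writes
#' TSVs, BEDs and a machine-readable `report.json` (which embeds the exact
#' panel definitions, all parameters, the seed and input checksums) into
#' `config$outDir`. Identical config + seed give identical reports.
#'
#' @param config a `RunConfig` from [runConfig()].
#' @param panels panels to profile (default [builtinPanels()]).
#' @return the report, invisibly (a nested list mirroring `report.json`).
#' @export
runEnrich <- function(config, panels = builtinPanels()) {
    stopifnot(inherits(config, "RunConfig"))
    inputs <- c(genome = config$genome, peaks = config$peaks,
                tss = config$tss,
                if (length(config$excludePeaks))
                    stats::setNames(config$excludePeaks,
                        sprintf("exclude%d", seq_along(config$excludePeaks))))
    missing <- inputs[!file.exists(inputs)]
    if (length(missing))
        stop("input file(s) not found: ", paste(missing, collapse = ", "),
             " (no outputs written)")

    .log("reading inputs")
    genome <- .stage("read_genome", .asGenome(config$genome))
    chromSizes <- stats::setNames(Biostrings::width(genome), names(genome))
    peaks <- .stage("read_peaks", readPeaks(config$peaks))
    tss <- .stage("read_tss", readTSS(config$tss))

    .log("building ", config$width, "-bp windows from ", length(peaks), " peaks")
    regions <- .stage("center_windows",
        centerWindows(peaks, width = config$width,
                      useSummit = config$useSummit, chromSizes = chromSizes))
    .log("promoter filter (<= ", config$maxUpstream, " bp upstream of ",
         length(tss), " TSS)")
    regions <- .stage("promoter_filter",
        promoterFilter(regions, tss, maxUpstream = config$maxUpstream,
                       mode = config$promoterMode))
    for (xp in config$excludePeaks) {
        other <- .stage("read_exclude_peaks", readPeaks(xp))
        regions <- .stage("exclude_overlapping",
                          excludeOverlapping(regions, other))
    }
    if (length(regions) == 0L)
        stop("stage 'regions' failed: no regions remain after filtering")
    names(regions) <- sprintf("region_%d", seq_along(regions))
    .log(length(regions), " analysis regions retained")

    chipSeqs <- .stage("extract_sequences", extractSequences(genome, regions))
    chipProfile <- .stage("profile_chip",
        profileRegions(chipSeqs, panels, strands = config$strands,
                       regions = regions))

    .log("sampling ", config$baselineN, " baseline regions (seed ",
         config$seed, ")")
    baseline <- .stage("sample_baseline",
        sampleBaseline(genome, n = config$baselineN, width = config$width,
                       seed = config$seed))
    baseSeqs <- .stage("extract_baseline", extractSequences(genome, baseline))
    baseProfile <- .stage("profile_baseline",
        profileRegions(baseSeqs, panels, strands = config$strands,
                       regions = baseline))

    pooledNames <- vapply(panels, panelName, "")
    enr <- lapply(pooledNames, function(p) .stage("fold_enrichment",
        foldEnrichment(chipProfile, baseProfile, p)))
    names(enr) <- pooledNames
    clu <- lapply(pooledNames, function(p) list(
        chip = .stage("cluster_distribution",
            clusterDistribution(chipProfile, p, config$clusterThreshold)),
        baseline = .stage("cluster_distribution",
            clusterDistribution(baseProfile, p, config$clusterThreshold))))
    names(clu) <- pooledNames
    cooc <- if (all(c("FIVE_GC", "CAGAC") %in% pooledNames))
        .stage("cooccurrence",
               cooccurrenceFraction(chipProfile, "FIVE_GC",
                                    config$clusterThreshold, "CAGAC", 1L))
    else NULL

    report <- list(
        parameters = unclass(config),
        inputs = lapply(seq_along(inputs), function(i)
            list(role = names(inputs)[i], path = unname(inputs[i]),
                 md5 = unname(tools::md5sum(inputs[i])))),
        panels = lapply(panels, function(p) list(
            name = panelName(p),
            patterns = as.character(panelPatterns(p)),
            five_prime_not = contextRule(p))),
        n_regions = list(chip = length(regions), baseline = length(baseline)),
        enrichment = lapply(enr, function(e) list(
            panel = e@panel, mean_chip = e@meanChip,
            mean_baseline = e@meanBaseline, fold = e@fold)),
        cluster_distribution = lapply(clu, function(x) list(
            chip = as.list(clusterFractions(x$chip)),
            baseline = as.list(clusterFractions(x$baseline)))),
        cooccurrence_five_gc_cagac = cooc)

    .stage("write_report", .writeReportBundle(
        config$outDir, report, regions, baseline, chipProfile, baseProfile,
        enr, clu))
    .log("report written to ", config$outDir)
    invisible(report)
}

.profileTsv <- function(profile, path) {
    rr <- SummarizedExperiment::rowRanges(profile)
    d <- cbind(data.frame(region = if (!is.null(names(rr))) names(rr)
                          else sprintf("region_%d", seq_along(rr)),
                          chrom = as.character(seqnames(rr)),
                          start = start(rr), end = end(rr)),
               as.data.frame(SummarizedExperiment::assay(profile, "counts")))
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.writeReportBundle <- function(outDir, report, regions, baseline,
                               chipProfile, baseProfile, enr, clu) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeRegionsBed(regions, file.path(outDir, "regions.bed"))
    writeRegionsBed(baseline, file.path(outDir, "baseline.bed"))
    .profileTsv(chipProfile, file.path(outDir, "profile_chip.tsv"))
    .profileTsv(baseProfile, file.path(outDir, "profile_baseline.tsv"))
    utils::write.table(do.call(rbind, lapply(enr, as.data.frame)),
                       file.path(outDir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cluDf <- do.call(rbind, lapply(names(clu), function(p) {
        rbind(cbind(set = "chip", as.data.frame(clu[[p]]$chip)),
              cbind(set = "baseline", as.data.frame(clu[[p]]$baseline)))
    }))
    utils::write.table(cluDf, file.path(outDir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    invisible(outDir)
}
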