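## Pipeline driver: wires all stages over an artifact directory, with a
## single master seed fanned out to per-stage child seeds. Every artifact
## is a plain-text file in one of the formats the io functions read, so a
## run is fully reproducible and inspectable.

#' Default PRDM9-like zinc-finger PWM
#'
#' A 15-position GC-rich position weight matrix standing in for a
#' zinc-finger DNA recognition motif, used as the default motif of the
#' synthetic pipeline. Each position strongly favours one base of a
#' GC-rich 15-mer.
#'
#' @param peak probability of the favoured base per position
#'   (default 0.85).
#' @return a [PWM-class] of length 15.
#' @export
defaultZfPwm <- function(peak = 0.85) {
  consensus <- strsplit("CCGCCGTGCCGCCGC", "")[[1]]
  base <- c(A = 1, C = 2, G = 3, T = 4)
  prob <- matrix((1 - peak) / 3, length(consensus), 4,
                 dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_along(consensus)) prob[i, base[consensus[i]]] <- peak
  PWM(prob, name = "ZF15")
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes the stages in dependency order: `simulate` (writes every
#' synthetic input: rate map, VCF + pedigree, FASTA, population VCF, TSS
#' table, peak BED, motif, truth JSON), `crossovers` (FID selection,
#' transmission phasing, detection, close-double-crossover QC),
#' `windowmap` (Monte-Carlo 1 Mb rates), `hotspots` (hotspot/coldspot
#' calls and recovery against truth), `features` (GC and pi of calls with
#' matched random-fragment nulls and rank-sum contrasts), `tsstest`
#' (midpoint-overlap permutation test) and `motiftest` (PWM enrichment).
#' Later stages read the artifacts of earlier ones from `outDir` and fail
#' with a message naming the missing stage. A full run is deterministic
#' given `config` (same seed, byte-identical `results.json`).
#'
#' @param config a [SimConfig-class].
#' @param outDir artifact directory (created if needed).
#' @param stages subset of
#'   `c("simulate", "crossovers", "windowmap", "hotspots", "features",
#'   "tsstest", "motiftest")`; default all, always executed in
#'   dependency order.
#' @param nMc Monte-Carlo replicates for the window map.
#' @param nSets permutation null sets for features and the TSS test.
#' @param verbose emit progress messages.
#' @return invisibly, the named list of results (also written as
#'   `results.json` in `outDir`).
#' @export
runPipeline <- function(config, outDir, stages = c("simulate",
    "crossovers", "windowmap", "hotspots", "features", "tsstest",
    "motiftest"), nMc = 50L, nSets = 1000L, verbose = TRUE) {
  allStages <- c("simulate", "crossovers", "windowmap", "hotspots",
                 "features", "tsstest", "motiftest")
  stages <- allStages[allStages %in% match.arg(stages, allStages,
                                               several.ok = TRUE)]
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(outDir, f)
  need <- function(f, stage) {
    if (!file.exists(pth(f)))
      stop("missing artifact '", f, "': run stage '", stage, "' first")
    pth(f)
  }
  say <- function(...) if (verbose) message("[recombMap] ", ...)
  results <- if (file.exists(pth("results.json")))
    jsonlite::read_json(pth("results.json"), simplifyVector = TRUE) else
    list()
  results$seed <- config@seed
  results$package_version <- as.character(packageVersion("recombMap"))
  genome <- GenomeIndex(config@chrom, config@chromLength)

  if ("simulate" %in% stages) {
    say("simulate: fine map, pedigree, sequences, variants, annotations")
    fine <- simulateFineMap(config)
    writeRateMap(fine$map, pth("rate_map.tsv"))
    pwm <- defaultZfPwm()
    writeMemePwm(pwm, pth("motif.meme"))
    seqs <- simulateSequences(config, fine$truth, pwm)
    truth <- seqs$truth
    Biostrings::writeXStringSet(seqs$sequences, pth("genome.fa"))
    popVars <- simulateVariants(config, truth)
    writeVcfFile(popVars, pth("population.vcf"))
    ## pedigree panel driven by the true (noiseless) landscape, scaled so
    ## the chromosome carries 1 Morgan in total (the genetic length of a
    ## typical pig chromosome; the desk-scale chromosome stands in for a
    ## whole one)
    trueMap <- FineScaleMap(config@chrom, snpPositions(fine$map),
                            truth@trueRates, units = "cM/Mb")
    avg <- chromosomeMeanRate(trueMap)
    targetMean <- 100 / (config@chromLength / 1e6)   # cM/Mb for 1 Morgan
    trueMap <- scaleRates(trueMap, targetMean / avg, units = "cM/Mb")
    writeRateMap(trueMap, pth("true_genetic_map.tsv"))
    ped <- simulatePedigreeMeioses(config, trueMap)
    writeVcfFile(ped$variants, pth("pedigree.vcf"))
    writePedigree(ped$pedigree, pth("pedigree.fam"))
    ann <- simulateAnnotations(config)
    writeTss(ann$tss, pth("tss.tsv"))
    writeBed(ann$peaks, pth("peaks.bed"))
    writeBed(trueHotspots(truth), pth("truth_hotspots.bed"))
    writeBed(trueColdspots(truth), pth("truth_coldspots.bed"))
    write.table(trueCrossovers(ped$truth), pth("truth_crossovers.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(motifPlants(truth), pth("truth_motif_plants.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(seed = config@seed,
      chrom = config@chrom, chrom_length = config@chromLength,
      n_hotspots = length(trueHotspots(truth)),
      n_coldspots = length(trueColdspots(truth)),
      n_true_crossovers = nrow(trueCrossovers(ped$truth))),
      pth("truth_summary.json"), auto_unbox = TRUE)
  }

  if ("crossovers" %in% stages) {
    say("crossovers: phasing, detection and QC")
    vt <- readVcfFile(need("pedigree.vcf", "simulate"))
    ped <- readPedigree(need("pedigree.fam", "simulate"))
    mset <- detectAndQc(vt, ped, minSupport = 3L, minSep = 3e6)
    write.table(crossovers(mset), pth("crossovers.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(meioses(mset), pth("meioses.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    results$n_meioses <- nMeioses(mset)
    results$n_crossovers <- nrow(crossovers(mset))
    results$acm <- nrow(crossovers(mset)) / nMeioses(mset)
  }

  if ("windowmap" %in% stages) {
    say("windowmap: Monte-Carlo 1 Mb rates")
    co <- read.table(need("crossovers.tsv", "crossovers"), header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)
    mm <- read.table(need("meioses.tsv", "crossovers"), header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)
    mset <- MeiosisSet(mm, co)
    wmap <- estimateWindowRatesMc(mset, genome, window = 1e6, nMc = nMc,
                                  seed = stageSeed(config@seed, "mc"))
    df <- cbind(bed0FromGr(windowRanges(wmap)),
                rate_cM_per_Mb = windowRates(wmap))
    write.table(df, pth("window_map.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    results$genetic_length_morgans <- geneticLength(wmap)
    ## correlation against the true landscape at the same scale
    trueMap <- readRateMap(need("true_genetic_map.tsv", "simulate"),
                           "per-snp-interval", chrom = config@chrom,
                           units = "cM/Mb")
    trueWin <- aggregateToWindows(trueMap, 1e6, config@chromLength)
    results$windowmap_spearman_vs_truth <- tryCatch(
      mapCorrelation(wmap, trueWin, "spearman")$estimate,
      error = function(e) NA_real_)  # genomes under 3 windows
  }

  if ("hotspots" %in% stages) {
    say("hotspots: calling and recovery scoring")
    map <- readRateMap(need("rate_map.tsv", "simulate"),
                       "per-snp-interval", chrom = config@chrom)
    hot <- callHotspots(map)
    cold <- callColdspots(map)
    writeBed(bedWithScore(hot, "hot"), pth("hotspots.bed"))
    writeBed(bedWithScore(cold, "cold"), pth("coldspots.bed"))
    truthHot <- readBed(need("truth_hotspots.bed", "simulate"))
    truthCold <- readBed(need("truth_coldspots.bed", "simulate"))
    rs <- recoveryScore(hot, truthHot)
    rsCold <- recoveryScore(cold, truthCold)
    results$n_hotspots <- length(hot)
    results$n_coldspots <- length(cold)
    results$mean_hotspot_size_bp <- if (length(hot))
      mean(GenomicRanges::width(hot)) else NA
    results$hotspot_sensitivity <- rs$sensitivity
    results$hotspot_precision <- rs$precision
    results$coldspot_sensitivity <- rsCold$sensitivity
    results$coldspot_precision <- rsCold$precision
  }

  if ("features" %in% stages) {
    say("features: GC, pi and matched random nulls")
    fasta <- Biostrings::readDNAStringSet(need("genome.fa", "simulate"))
    names(fasta) <- sub("\\s.*", "", names(fasta))
    popVars <- readVcfFile(need("population.vcf", "simulate"))
    hot <- readBed(need("hotspots.bed", "hotspots"))
    cold <- readBed(need("coldspots.bed", "hotspots"))
    ftHot <- featureTable(fasta, popVars, hot, "hotspot")
    ftCold <- featureTable(fasta, popVars, cold, "coldspot")
    ## matched random-fragment nulls (hotspot sizes)
    nulls <- sampleMatchedRandomIntervals(genome,
      GenomicRanges::width(hot), nSets = nSets,
      seed = stageSeed(config@seed, "nulls"))
    nullGc <- vapply(nulls, function(gr)
      mean(gcOfIntervals(fasta, gr), na.rm = TRUE), numeric(1))
    nullPi <- vapply(nulls, function(gr)
      mean(piOfIntervals(popVars, gr)), numeric(1))
    ft <- rbind(ftHot, ftCold)
    write.table(ft, pth("features.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(set = seq_along(nullGc), gc = nullGc,
                           pi = nullPi), pth("feature_nulls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    results$hotspot_gc_pct <- 100 * mean(ftHot$gc, na.rm = TRUE)
    results$coldspot_gc_pct <- 100 * mean(ftCold$gc, na.rm = TRUE)
    results$random_gc_pct <- 100 * mean(nullGc)
    results$hotspot_pi <- mean(ftHot$pi)
    results$coldspot_pi <- mean(ftCold$pi)
    results$gc_hot_vs_cold_p <- ranksumCompare(ftHot$gc, ftCold$gc)$p
    results$pi_hot_vs_cold_p <- ranksumCompare(ftHot$pi, ftCold$pi)$p
    results$gc_hot_vs_random_p <- empiricalP(mean(ftHot$gc, na.rm = TRUE),
                                             nullGc, "upper")
    results$pi_cold_vs_random_p <- empiricalP(mean(ftCold$pi), nullPi,
                                              "lower")
  }

  if ("tsstest" %in% stages) {
    say("tsstest: midpoint-overlap permutation test")
    hot <- readBed(need("hotspots.bed", "hotspots"))
    tss <- readTss(need("tss.tsv", "simulate"))
    win <- buildTssWindows(tss, 3000, genome)
    obs <- countMidpointOverlaps(hot, win)
    tt <- randomPointNullTest(length(hot), obs, win, genome,
                              nSets = nSets,
                              seed = stageSeed(config@seed, "tss"))
    peaks <- readBed(need("peaks.bed", "simulate"))
    po <- intervalOverlapStats(peaks, win)
    ho <- intervalOverlapStats(hot, peaks)
    write.table(hotspotTssTable(hot, win), pth("hotspot_tss.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    results$tss_observed_overlaps <- tt$observed
    results$tss_overlap_pct <- 100 * tt$observed / max(length(hot), 1)
    results$tss_null_mean <- tt$nullMean
    results$tss_empirical_p <- tt$empiricalP
    results$tss_t_test_p <- tt$tTestP
    results$tss_direction <- tt$direction
    results$peak_tss_overlap_pct <- 100 * po$fractionA
    results$hotspot_peak_overlap_pct <- 100 * ho$fractionA
  }

  if ("motiftest" %in% stages) {
    say("motiftest: PWM enrichment, hotspots vs coldspots")
    fasta <- Biostrings::readDNAStringSet(need("genome.fa", "simulate"))
    names(fasta) <- sub("\\s.*", "", names(fasta))
    pwm <- readMemePwm(need("motif.meme", "simulate"))
    hot <- readBed(need("hotspots.bed", "hotspots"))
    cold <- readBed(need("coldspots.bed", "hotspots"))
    hs <- extractIntervalSequences(fasta, hot)
    cs <- extractIntervalSequences(fasta, cold)
    er <- pwmEnrichmentTest(hs, cs, pwm)
    results$motif_p <- er$p
    results$motif_minus_log10_p <- -log10(max(er$p, 1e-300))
  }

  jsonlite::write_json(results, pth("results.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(results)
}

## BED6-ready GRanges: name and 0-1000 capped score (fold x 100)
bedWithScore <- function(gr, label) {
  if (!length(gr)) return(gr)
  fold <- S4Vectors::mcols(gr)$foldOverMean
  if (is.null(fold)) fold <- rep(0, length(gr))
  S4Vectors::mcols(gr) <- NULL
  S4Vectors::mcols(gr)$name <- sprintf("%s%05d", label, seq_along(gr))
  S4Vectors::mcols(gr)$score <- pmin(round(fold * 100), 1000)
  gr
}
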