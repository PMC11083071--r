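uniformGmap <- function(len = 5e7, rate = 2) {
  gr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(1, len, by = 1e6), width = 1e6))
  S4Vectors::mcols(gr)$rate <- rate
  WindowMap(gr)
}

test_that("fine map generator honours folds, noise and determinism", {
  cfg <- simConfig(seed = 11, chromLength = 2e6, hotspotCount = 4L,
                   coldspotCount = 2L, rateNoiseSd = 0)
  sim <- simulateFineMap(cfg)
  r <- intervalRates(sim$map)
  mids <- (snpPositions(sim$map)[-length(snpPositions(sim$map))] +
             snpPositions(sim$map)[-1]) / 2
  midGr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(mids + 1, mids + 1))
  inHot <- IRanges::overlapsAny(midGr, trueHotspots(sim$truth))
  inCold <- IRanges::overlapsAny(midGr, trueColdspots(sim$truth))
  expect_true(all(r[inHot] == 0.001 * 50))
  expect_true(all(r[inCold] == 0.001 * 0.02))
  expect_true(all(r[!inHot & !inCold] == 0.001))
  ## mean rate inside hotspots / background = fold exactly (no noise)
  expect_equal(mean(r[inHot]) / 0.001, 50)

  sim2 <- simulateFineMap(cfg)
  expect_identical(snpPositions(sim$map), snpPositions(sim2$map))
  expect_identical(intervalRates(sim$map), intervalRates(sim2$map))

  ## impossible plant raises
  expect_error(simulateFineMap(simConfig(chromLength = 3e4,
    hotspotCount = 20L, hotspotWidthRange = c(2000, 3000),
    coldspotCount = 0L)), "fit")
})

test_that("meiosis counts are Poisson with the map length as mean", {
  cfg <- simConfig(seed = 5, chromLength = 5e7, markerSpacing = 5e4,
                   nFids = 100L, offspringPerFid = 10L,
                   genotypeErrorRate = 0)
  sim <- simulatePedigreeMeioses(cfg, uniformGmap())  # 1 Morgan
  nMei <- cfg@nFids * cfg@offspringPerFid
  meanCo <- nrow(trueCrossovers(sim$truth)) / nMei
  se <- sqrt(1 / nMei)
  expect_lt(abs(meanCo - 1), 3 * se)
})

test_that("crossover positions follow the inverse map CDF", {
  ## uniform map -> positions uniform (KS)
  cfg <- simConfig(seed = 6, chromLength = 5e7, markerSpacing = 5e4,
                   nFids = 100L, offspringPerFid = 50L,
                   genotypeErrorRate = 0)
  sim <- simulatePedigreeMeioses(cfg, uniformGmap())
  pos <- trueCrossovers(sim$truth)$pos
  expect_gt(length(pos), 1000)
  ks <- suppressWarnings(ks.test(pos / 5e7, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("offspring genotypes are Mendelian-consistent without errors", {
  cfg <- simConfig(seed = 7, chromLength = 1e7, markerSpacing = 1e5,
                   nFids = 5L, offspringPerFid = 4L,
                   genotypeErrorRate = 0)
  sim <- simulatePedigreeMeioses(cfg, uniformGmap(1e7, 10))
  g <- genotypes(sim$variants)
  ped <- sim$pedigree
  kids <- ped[!is.na(ped$sire) & !is.na(ped$dam) &
                ped$sire %in% colnames(g) | (!is.na(ped$dam) &
                ped$dam %in% colnames(g)), ]
  kids <- ped[ped$id %in% colnames(g) &
                (!is.na(ped$sire) | !is.na(ped$dam)), ]
  for (k in seq_len(nrow(kids))) {
    kid <- kids$id[k]
    for (par in c(kids$sire[k], kids$dam[k])) {
      if (is.na(par) || !par %in% colnames(g)) next
      ## parent hom 0 forbids kid 2 and vice versa
      expect_false(any(g[, par] == 0 & g[, kid] == 2))
      expect_false(any(g[, par] == 2 & g[, kid] == 0))
    }
  }
  expect_error(
    simulatePedigreeMeioses(cfg, WindowMap({
      gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1e7))
      S4Vectors::mcols(gr)$rate <- 0
      gr
    })), "Morgans")
})

test_that("sequence generator honours GC and motif plant rates", {
  pwm <- defaultZfPwm()
  cfg <- simConfig(seed = 8, chromLength = 5e5, hotspotCount = 10L,
                   coldspotCount = 5L, gcHotspot = 1.0,
                   motifPlantRateHot = 1.0, motifPlantRateCold = 0)
  sim <- simulateFineMap(cfg)
  sq <- simulateSequences(cfg, sim$truth, pwm)
  hot <- extractIntervalSequences(sq$sequences, trueHotspots(sq$truth))
  ## gc 1.0 -> hotspot sequences only G/C outside the planted motif,
  ## and every hotspot contains an exact consensus match
  cons <- pwmConsensus(pwm)
  rcons <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cons)))
  hits <- vapply(as.character(hot), function(s)
    grepl(cons, s, fixed = TRUE) || grepl(rcons, s, fixed = TRUE),
    logical(1))
  expect_true(all(hits))
  cold <- extractIntervalSequences(sq$sequences, trueColdspots(sq$truth))
  chits <- vapply(as.character(cold), function(s)
    grepl(cons, s, fixed = TRUE) || grepl(rcons, s, fixed = TRUE),
    logical(1))
  expect_false(any(chits))
  gcHot <- gcOfIntervals(sq$sequences, trueHotspots(sq$truth))
  ## only the planted 15-mer can dilute pure G/C composition
  expect_true(all(gcHot > 0.95))
  expect_equal(nrow(motifPlants(sq$truth)), 10L)

  ## background GC within 3 binomial SE over ~100 kb
  cfg2 <- simConfig(seed = 9, chromLength = 1e5, hotspotCount = 0L,
                    coldspotCount = 0L)
  sim2 <- simulateFineMap(cfg2)
  sq2 <- simulateSequences(cfg2, sim2$truth, pwm)
  gc <- gcOfIntervals(sq2$sequences,
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1e5)))
  se <- sqrt(0.4296 * (1 - 0.4296) / 1e5)
  expect_lt(abs(gc - 0.4296), 3 * se)
})

test_that("variant generator creates the requested diversity structure", {
  ## coldspot density 0 -> pi exactly 0 in every coldspot
  cfg <- simConfig(seed = 10, chromLength = 1e6, hotspotCount = 3L,
                   coldspotCount = 3L, siteDensityCold = 0,
                   siteDensityHot = 0.01)
  sim <- simulateFineMap(cfg)
  vt <- simulateVariants(cfg, sim$truth)
  piCold <- piOfIntervals(vt, trueColdspots(sim$truth))
  expect_equal(as.numeric(piCold), rep(0, 3))

  ## n = 2 haplotypes forces j = 1 and site pi = 1
  cfg2 <- simConfig(seed = 11, chromLength = 1e5, hotspotCount = 0L,
                    coldspotCount = 0L, nHaplotypes = 2L)
  sim2 <- simulateFineMap(cfg2)
  vt2 <- simulateVariants(cfg2, sim2$truth)
  h <- haplotypeMatrix(vt2)
  expect_true(all(rowSums(h) == 1))
})

test_that("equal site densities give a calibrated hot/cold pi contrast", {
  ## under equal densities the rank-sum test should be non-significant in
  ## at least 90% of seeds
  nonsig <- 0
  for (s in 1:100) {
    cfg <- simConfig(seed = 2000 + s, chromLength = 4e5,
                     hotspotCount = 8L, coldspotCount = 8L,
                     hotspotWidthRange = c(2000, 3000),
                     coldspotWidthRange = c(2000, 3000),
                     siteDensityHot = 0.012, siteDensityCold = 0.012,
                     nHaplotypes = 20L)
    sim <- simulateFineMap(cfg)
    vt <- simulateVariants(cfg, sim$truth)
    a <- piOfIntervals(vt, trueHotspots(sim$truth))
    b <- piOfIntervals(vt, trueColdspots(sim$truth))
    if (ranksumCompare(a, b)$p >= 0.05) nonsig <- nonsig + 1
  }
  expect_gte(nonsig, 90)
})

test_that("annotation generator controls the peak-TSS fraction", {
  gi <- GenomeIndex("chr1", 1e7)
  cfg <- simConfig(seed = 12, chromLength = 1e7, nGenes = 50L,
                   nPeaks = 40L, peakTssFraction = 1.0)
  ann <- simulateAnnotations(cfg)
  win <- buildTssWindows(ann$tss, 3000, gi)
  ov <- intervalOverlapStats(ann$peaks, win)
  expect_equal(ov$fractionA, 1.0)

  ## fraction 0 on a large genome: close to the chance expectation
  cfg0 <- simConfig(seed = 13, chromLength = 1e8, nGenes = 50L,
                    nPeaks = 400L, peakTssFraction = 0)
  ann0 <- simulateAnnotations(cfg0)
  win0 <- buildTssWindows(ann0$tss, 3000, GenomeIndex("chr1", 1e8))
  ov0 <- intervalOverlapStats(ann0$peaks, win0)
  pChance <- sum(GenomicRanges::width(GenomicRanges::reduce(win0)) +
                   1648) / 1e8
  se <- sqrt(pChance * (1 - pChance) / 400)
  expect_lt(abs(ov0$fractionA - pChance), 4 * se)

  expect_error(simulateAnnotations(simConfig(nGenes = 0L,
    peakTssFraction = 0.5)), "nGenes")
})

test_that("generators are deterministic given the seed", {
  cfg <- simConfig(seed = 99, chromLength = 3e5, hotspotCount = 2L,
                   coldspotCount = 1L)
  s1 <- simulateFineMap(cfg); s2 <- simulateFineMap(cfg)
  expect_identical(intervalRates(s1$map), intervalRates(s2$map))
  v1 <- simulateVariants(cfg, s1$truth)
  v2 <- simulateVariants(cfg, s2$truth)
  expect_identical(variantSites(v1), variantSites(v2))
  expect_identical(haplotypeMatrix(v1), haplotypeMatrix(v2))
  a1 <- simulateAnnotations(cfg); a2 <- simulateAnnotations(cfg)
  expect_identical(a1$tss, a2$tss)
})
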