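gmapUniform <- function(len = 5e7, rate = 2) {
  gr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(1, len, by = 1e6), width = 1e6))
  S4Vectors::mcols(gr)$rate <- rate
  WindowMap(gr)
}

test_that("FID selection applies the parent/offspring rule", {
  ped <- data.frame(
    id = c("knownP2", "founder3", "founder4", "X",
           paste0("k", 1:2), paste0("f3_", 1:3), paste0("f4_", 1:4)),
    sire = c("X", NA, NA, NA, rep("knownP2", 2), rep("founder3", 3),
             rep("founder4", 4)),
    dam = NA_character_,
    sex = "male", population = "p")
  sel <- selectFids(ped)
  expect_true("knownP2" %in% sel)     # known parent, 2 offspring
  expect_false("founder3" %in% sel)   # no parent, 3 offspring
  expect_true("founder4" %in% sel)    # no parent, 4 offspring
  expect_false("X" %in% sel)          # no parent, 1 offspring
  ## empty result allowed
  expect_length(selectFids(ped[ped$id == "X", , drop = FALSE]), 0)
})

test_that("transmission phasing resolves forced transmissions", {
  ## FID het at all markers, mates homozygous -> everything informative
  sites <- data.frame(chrom = "chr1", pos = c(100, 200, 300), ref = "A",
                      alt = "G", qual = 99, depth = NA)
  g <- cbind(FID = c(1L, 1L, 1L), M1 = c(0L, 0L, 0L), M2 = c(2L, 2L, 2L),
             K1 = c(1L, 1L, 0L),  # received 1,1,0 from FID
             K2 = c(2L, 1L, 1L))  # received 0,... minus mate allele 1
  ped <- data.frame(id = c("FID", "M1", "M2", "K1", "K2"),
                    sire = c(NA, NA, NA, "FID", "FID"),
                    dam = c(NA, NA, NA, "M1", "M2"),
                    sex = c("male", "female", "female", "unknown",
                            "unknown"),
                    population = "p")
  os <- phaseByTransmission(VariantTable(sites, g), ped, "FID")
  ## transmitted alleles: K1 = 1,1,0 (mate hom 0); K2 = 1,0,0 (mate hom 2)
  ## anchor: first informative marker of K1 defines haplotype 1
  expect_equal(unname(os$origins[1, "K1"]), 1L)
  expect_equal(unname(os$origins[1, "K2"]), 1L)  # same allele transmitted
  expect_equal(sum(is.na(os$origins)), 0L)       # all forced
  expect_equal(os$mendelErrors, 0L)
  ## FID homozygous marker is uninformative
  g2 <- g; g2[2, "FID"] <- 0L
  os2 <- phaseByTransmission(VariantTable(sites, g2), ped, "FID")
  expect_true(all(is.na(os2$origins[2, ])))
  ## Mendelian inconsistency is counted and set missing
  g3 <- g; g3[1, "M1"] <- 0L; g3[1, "K1"] <- 2L
  os3 <- phaseByTransmission(VariantTable(sites, g3), ped, "FID")
  expect_gte(os3$mendelErrors, 1L)
  expect_error(phaseByTransmission(VariantTable(sites, g[, 1:3]),
                                   ped[1:3, ], "FID"), "offspring")
})

test_that("phasing recovers simulated origins up to a global label swap", {
  cfg <- simConfig(seed = 21, chromLength = 2e7, markerSpacing = 5e4,
                   nFids = 4L, offspringPerFid = 6L,
                   genotypeErrorRate = 0)
  sim <- simulatePedigreeMeioses(cfg, gmapUniform(2e7, 5))
  tr <- trueCrossovers(sim$truth)
  for (fid in c("FID001", "FID002")) {
    os <- phaseByTransmission(sim$variants, sim$pedigree, fid)
    for (k in seq_along(os$offspring)) {
      mid <- paste0(fid, "_", os$offspring[k])
      truePos <- sort(tr$pos[tr$meiosis == mid])
      o <- os$origins[, k]
      inf <- which(!is.na(o))
      ## switches in the inferred origin sequence must happen exactly at
      ## the true crossover positions (between flanking markers)
      sw <- inf[which(diff(o[inf]) != 0)]
      swNext <- inf[which(diff(o[inf]) != 0) + 1]
      expect_equal(length(sw), length(truePos))
      if (length(truePos)) {
        expect_true(all(os$positions[sw] <= truePos &
                          truePos <= os$positions[swNext]))
      }
    }
  }
})

test_that("run-based detection applies the min-support rule", {
  pos <- seq(0, 500, by = 100)
  ev <- detectCrossovers(c(1, 1, 1, 2, 2, 2), minSupport = 3,
                         positions = pos)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$left, 200)
  expect_equal(ev$right, 300)

  ev2 <- detectCrossovers(c(1, 1, 2, 1, 1), minSupport = 2,
                          positions = pos[1:5])
  expect_equal(nrow(ev2), 0L)

  ev3 <- detectCrossovers(c(1, 1, 2, 2, 1, 1), minSupport = 2,
                          positions = pos)
  expect_equal(nrow(ev3), 2L)
  expect_equal(ev3$left, c(100, 300))
  expect_equal(ev3$right, c(200, 400))

  ## all-missing chromosome -> empty
  expect_equal(nrow(detectCrossovers(rep(NA_integer_, 5),
                                     positions = pos[1:5])), 0L)
  ## missing markers are transparent to run counting
  ev4 <- detectCrossovers(c(1, NA, 1, 1, 2, NA, 2, 2), minSupport = 3,
                          positions = seq(0, 700, by = 100))
  expect_equal(nrow(ev4), 1L)
  expect_equal(ev4$left, 300)
  expect_equal(ev4$right, 400)
})

test_that("detector meets its contract on fully informative origins", {
  ## chip-grid origin sequences with full informativeness: >= 99% of true
  ## crossovers bounded, none spurious
  set.seed(31)
  markers <- seq(0, 5e7 - 1, by = 5e4)
  nDetected <- 0; nTrue <- 0; allBounded <- TRUE; spurious <- 0
  for (m in 1:300) {
    nco <- rpois(1, 1)
    copos <- sort(runif(nco, 0, 5e7))
    origin <- (findInterval(markers, copos) +
                 sample(0:1, 1)) %% 2 + 1
    ev <- detectCrossovers(origin, minSupport = 3, positions = markers)
    nTrue <- nTrue + nco
    for (p in copos) {
      hit <- any(ev$left <= p & p <= ev$right)
      nDetected <- nDetected + hit
    }
    spurious <- spurious +
      sum(!vapply(seq_len(nrow(ev)), function(i)
        any(copos >= ev$left[i] & copos <= ev$right[i]), logical(1)))
  }
  expect_gte(nDetected / nTrue, 0.99)
  expect_equal(spurious, 0)
})

test_that("close double crossovers are masked iteratively", {
  mk <- function(pos) {
    mm <- data.frame(meiosis = "m1", fid = "f", offspring = "o",
                     sex = "male", population = "p")
    co <- data.frame(meiosis = "m1", chrom = "chr1",
                     left = pos - 1e4, right = pos + 1e4, sex = "male")
    MeiosisSet(mm, co)
  }
  ## 10.0 and 12.5 Mb -> both removed, region masked
  m <- maskCloseDoubleCrossovers(mk(c(10e6, 12.5e6)))
  expect_equal(nrow(crossovers(m)), 0L)
  expect_equal(nrow(maskedRegions(m)), 1L)
  expect_equal(maskedRegions(m)$start, 10e6 - 1e4)
  expect_equal(maskedRegions(m)$end, 12.5e6 + 1e4)
  ## 10.0 and 13.5 Mb -> both kept
  m2 <- maskCloseDoubleCrossovers(mk(c(10e6, 13.5e6)))
  expect_equal(nrow(crossovers(m2)), 2L)
  ## 10, 12.5, 20 -> pair removed, 20 kept
  m3 <- maskCloseDoubleCrossovers(mk(c(10e6, 12.5e6, 20e6)))
  expect_equal(nrow(crossovers(m3)), 1L)
  expect_equal(crossovers(m3)$left, 20e6 - 1e4)
  ## iterative: 10, 12.5, 14 -> (10,12.5) masked, 14 survives alone
  m4 <- maskCloseDoubleCrossovers(mk(c(10e6, 12.5e6, 14e6)))
  expect_equal(nrow(crossovers(m4)), 1L)
  ## chain 10, 12.5, 13.5: (10,12.5) out, 13.5 kept
  m5 <- maskCloseDoubleCrossovers(mk(c(10e6, 12.5e6, 13.5e6)))
  expect_equal(nrow(crossovers(m5)), 1L)
})

test_that("QC leaves no surviving pair below the separation threshold", {
  cfg <- simConfig(seed = 23, chromLength = 3e7, markerSpacing = 5e4,
                   nFids = 10L, offspringPerFid = 10L,
                   genotypeErrorRate = 0)
  sim <- simulatePedigreeMeioses(cfg, gmapUniform(3e7, 5))  # 1.5 M
  m <- detectAndQc(sim$variants, sim$pedigree)
  co <- crossovers(m)
  for (key in unique(co$meiosis)) {
    mids <- sort((co$left[co$meiosis == key] +
                    co$right[co$meiosis == key]) / 2)
    if (length(mids) > 1) expect_true(all(diff(mids) >= 3e6))
  }
})

test_that("Monte-Carlo window rates allocate crossover mass correctly", {
  gi <- GenomeIndex("chr1", 3e6)
  mm <- data.frame(meiosis = sprintf("m%03d", 1:100), fid = "f",
                   offspring = sprintf("o%03d", 1:100), sex = "male",
                   population = "p")
  ## one crossover fully inside window 2
  co <- data.frame(meiosis = "m001", chrom = "chr1", left = 1.2e6,
                   right = 1.4e6, sex = "male")
  wm <- estimateWindowRatesMc(MeiosisSet(mm, co), gi, 1e6, nMc = 10,
                              seed = 3)
  expect_equal(windowRates(wm), c(0, 1, 0))
  expect_equal(geneticLength(wm), 0.01)

  ## interval straddling two windows equally: ~0.5 each
  co2 <- data.frame(meiosis = "m001", chrom = "chr1", left = 0.9e6,
                    right = 1.1e6, sex = "male")
  wm2 <- estimateWindowRatesMc(MeiosisSet(mm, co2), gi, 1e6,
                               nMc = 2000, seed = 4)
  counts <- S4Vectors::mcols(windowRanges(wm2))$count
  expect_lt(abs(counts[1] - 0.5), 3 * sqrt(0.25 / 2000))
  expect_equal(sum(counts), 1)

  ## determinism
  wm3 <- estimateWindowRatesMc(MeiosisSet(mm, co2), gi, 1e6, nMc = 1,
                               seed = 11)
  wm4 <- estimateWindowRatesMc(MeiosisSet(mm, co2), gi, 1e6, nMc = 1,
                               seed = 11)
  expect_identical(windowRates(wm3), windowRates(wm4))
  expect_error(estimateWindowRatesMc(MeiosisSet(mm[0, ], co[0, ]), gi),
               "no meioses")
})

test_that("window rates conserve total crossover mass", {
  cfg <- simConfig(seed = 25, chromLength = 2e7, markerSpacing = 5e4,
                   nFids = 10L, offspringPerFid = 10L,
                   genotypeErrorRate = 0)
  sim <- simulatePedigreeMeioses(cfg, gmapUniform(2e7, 5))
  m <- detectAndQc(sim$variants, sim$pedigree)
  wm <- estimateWindowRatesMc(m, GenomeIndex("chr1", 2e7), 1e6,
                              nMc = 20, seed = 5)
  mb <- GenomicRanges::width(windowRanges(wm)) / 1e6
  expect_equal(sum(windowRates(wm) * mb) / 100,
               nrow(crossovers(m)) / nMeioses(m), tolerance = 1e-9)
})

test_that("more Monte-Carlo replicates shrink estimator variance", {
  gi <- GenomeIndex("chr1", 2e6)
  mm <- data.frame(meiosis = "m1", fid = "f", offspring = "o",
                   sex = "male", population = "p")
  co <- data.frame(meiosis = "m1", chrom = "chr1", left = 0.5e6,
                   right = 1.5e6, sex = "male")
  ms <- MeiosisSet(mm, co)
  varOf <- function(nMc) {
    est <- vapply(1:40, function(s)
      windowRates(estimateWindowRatesMc(ms, gi, 1e6, nMc = nMc,
                                        seed = s))[1], numeric(1))
    var(est)
  }
  expect_lt(varOf(64), varOf(1))
})

test_that("ACM F-tests match a textbook one-way ANOVA", {
  mkSet <- function(acms, pops, sexes = "male") {
    n <- length(acms)
    mm <- do.call(rbind, lapply(seq_len(n), function(i)
      data.frame(meiosis = sprintf("f%02d_o%d", i, 1:10),
                 fid = sprintf("f%02d", i),
                 offspring = sprintf("f%02d_o%d", i, 1:10),
                 sex = sexes, population = pops[i])))
    co <- do.call(rbind, lapply(seq_len(n), function(i) {
      k <- acms[i] * 10                  # events spread over 10 meioses
      if (k == 0) return(NULL)
      data.frame(meiosis = sprintf("f%02d_o%d", i,
                                   (seq_len(k) - 1) %% 10 + 1),
                 chrom = "chr1", left = 1e6 * seq_len(k),
                 right = 1e6 * seq_len(k) + 1e5, sex = sexes)
    }))
    MeiosisSet(mm, co)
  }
  ## identical groups -> F = 0, p = 1
  m <- mkSet(c(1, 2, 3, 1, 2, 3), rep(c("A", "B"), each = 3))
  res <- acmCompare(m)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)

  ## {10,12,14} vs {20,22,24} against stats::oneway.test
  m2 <- mkSet(c(10, 12, 14, 20, 22, 24), rep(c("A", "B"), each = 3))
  res2 <- acmCompare(m2)
  ref <- oneway.test(c(10, 12, 14, 20, 22, 24) ~
                       rep(c("A", "B"), each = 3), var.equal = TRUE)
  expect_equal(res2$F, unname(ref$statistic))
  expect_equal(res2$p, ref$p.value)
  ## and against the hand-computed classic ANOVA: F = 150/(8/3) ...
  ## between SS = 2*3*25 wait: groups means 12 and 22, grand 17,
  ## SSB = 3*25+3*25 = 150, SSW = 8+8 = 16, F = 150/(16/4) = 37.5
  expect_equal(res2$F, 37.5)

  ## one group only -> empty table
  m3 <- mkSet(c(1, 2), c("A", "A"))
  expect_equal(nrow(acmCompare(m3)), 0L)
  ## group with one FID is skipped with a warning
  m4 <- mkSet(c(1, 2, 3), c("A", "A", "B"))
  expect_warning(res4 <- acmCompare(m4), "< 2 FIDs")
  expect_equal(nrow(res4), 0L)
})
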