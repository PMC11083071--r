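test_that("GC content counts unambiguous bases only", {
  dss <- Biostrings::DNAStringSet(c(chr1 = "ATATGCGCACGNNNNN"))
  iv <- function(s, e) GenomicRanges::GRanges("chr1",
                                              IRanges::IRanges(s, e))
  expect_equal(gcOfIntervals(dss, iv(1, 4)), 0)       # ATAT
  expect_equal(gcOfIntervals(dss, iv(5, 8)), 1)       # GCGC
  expect_equal(gcOfIntervals(dss, iv(9, 12)), 2 / 3)  # ACGN
  expect_true(is.na(gcOfIntervals(dss, iv(13, 16))))  # NNNN
  expect_error(gcOfIntervals(dss, iv(10, 20)), "beyond")
  expect_error(gcOfIntervals(dss,
    GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 2))), "absent")
})

test_that("GC is strand-invariant", {
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
             collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  iv <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 500))
  expect_equal(gcOfIntervals(Biostrings::DNAStringSet(c(chr1 = s)), iv),
               gcOfIntervals(Biostrings::DNAStringSet(c(chr1 = rc)), iv))
})

test_that("pi matches the worked example and duplication formula", {
  sites <- data.frame(chrom = "chr1", pos = 50, ref = "A", alt = "G",
                      qual = 99, depth = NA)
  iv <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
  ## n = 4, j = 2: site pi = 2*2*2/(4*3) = 2/3; over 100 bp = 0.006667
  h4 <- matrix(c(1L, 1L, 0L, 0L), 1)
  expect_equal(as.numeric(piOfIntervals(VariantTable(sites,
    haplotypes = h4), iv)), 8 / 12 / 100)
  ## duplicating every haplotype: j 2 -> 4 of n 8: 32/56
  h8 <- matrix(rep(c(1L, 1L, 0L, 0L), 2), 1)
  expect_equal(as.numeric(piOfIntervals(VariantTable(sites,
    haplotypes = h8), iv)), 32 / 56 / 100)
  ## no segregating sites -> 0
  empty <- VariantTable(sites[0, ],
    haplotypes = matrix(integer(0), 0, 4))
  expect_equal(as.numeric(piOfIntervals(empty, iv)), 0)
})

test_that("pi equals the brute-force pairwise oracle", {
  set.seed(6)
  for (rep in 1:20) {
    nh <- sample(3:10, 1); ns <- sample(5:50, 1)
    pos <- sort(sample(1:2000, ns))
    hap <- matrix(rbinom(ns * nh, 1, runif(1, 0.1, 0.6)), ns, nh)
    hap[runif(ns * nh) < 0.05] <- NA  # some missing haplotype calls
    sites <- data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "G",
                        qual = 99, depth = NA)
    vt <- VariantTable(sites, haplotypes = hap)
    iv <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 1600))
    expect_equal(as.numeric(piOfIntervals(vt, iv)),
                 bruteForcePi(hap, pos, 101, 1600), tolerance = 1e-12)
  }
})

test_that("pi from diploid genotypes uses two haplotypes per sample", {
  sites <- data.frame(chrom = "chr1", pos = 10, ref = "A", alt = "G",
                      qual = 99, depth = NA)
  g <- matrix(c(1L, 1L), 1)  # two hets: n = 4, j = 2
  iv <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
  expect_equal(as.numeric(piOfIntervals(VariantTable(sites, g), iv)),
               8 / 12 / 100)
})

test_that("matched random fragments preserve sizes and avoid the mask", {
  gi <- GenomeIndex("chr1", 1e6)
  sets <- sampleMatchedRandomIntervals(gi, rep(100, 5), nSets = 20,
                                       seed = 3)
  expect_length(sets, 20)
  for (s in sets) expect_equal(GenomicRanges::width(s), rep(100, 5))

  ## exclusion mask covering all but one placement forces that placement
  mask <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 301), c(200, 1e6)))
  sets2 <- sampleMatchedRandomIntervals(gi, 100, nSets = 10, seed = 4,
                                        exclude = mask)
  for (s in sets2) expect_equal(GenomicRanges::start(s), 201)

  ## unplaceable size errors
  expect_error(sampleMatchedRandomIntervals(gi, 2e6, nSets = 1,
                                            seed = 1), "exceeds")
  fullMask <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1e6))
  expect_error(sampleMatchedRandomIntervals(gi, 100, nSets = 1, seed = 1,
    exclude = fullMask), "no valid placement")
  ## a fragment larger than the remaining gap is also unplaceable
  expect_error(sampleMatchedRandomIntervals(gi, 150, nSets = 1, seed = 1,
    exclude = mask), "no valid placement")
})

test_that("random fragment GC matches the genome average", {
  cfg <- simConfig(seed = 14, chromLength = 2e5, hotspotCount = 0L,
                   coldspotCount = 0L)
  sim <- simulateFineMap(cfg)
  sq <- simulateSequences(cfg, sim$truth, defaultZfPwm())
  gi <- GenomeIndex("chr1", 2e5)
  sets <- sampleMatchedRandomIntervals(gi, rep(500, 10), nSets = 100,
                                       seed = 5)
  gcs <- vapply(sets, function(s) mean(gcOfIntervals(sq$sequences, s)),
                numeric(1))
  se <- sqrt(0.4296 * (1 - 0.4296) / (100 * 10 * 500))
  expect_lt(abs(mean(gcs) - 0.4296), 4 * se)
})

test_that("empirical p uses the add-one rank convention", {
  null999 <- seq_len(999)
  expect_equal(empiricalP(1000.5, null999, "upper"), 1 / 1000)
  expect_equal(empiricalP(0, null999, "lower"), 1 / 1000)
  ## 5 of 99 nulls >= observed -> (5+1)/100
  null99 <- c(rep(1, 94), rep(10, 5))
  expect_equal(empiricalP(9, null99, "upper"), 6 / 100)
  ## observed at the median -> two-sided ~ 1
  expect_equal(empiricalP(500, null999, "two-sided"), 1)
  expect_lte(empiricalP(500, null999, "two-sided"), 1)
})

test_that("rank-sum comparison handles exact, tied and swapped cases", {
  ## {1,2,3} vs {10,11,12}: U = 0, exact two-sided p = 2/choose(6,3)
  r <- ranksumCompare(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$U, 0)
  expect_equal(r$p, 2 / choose(6, 3))
  ## identical samples: U = n1 n2 / 2 territory, p not small
  set.seed(8)
  x <- rnorm(30)
  ri <- ranksumCompare(x, x)
  expect_gt(ri$p, 0.9)
  ## all values tied across both -> p = 1
  rt <- ranksumCompare(rep(2, 5), rep(2, 7))
  expect_equal(rt$p, 1)
  expect_equal(rt$U, 5 * 7 / 2)
  ## symmetry of the two-sided p
  a <- rnorm(20); b <- rnorm(25, 0.5)
  expect_equal(ranksumCompare(a, b)$p, ranksumCompare(b, a)$p)
  expect_error(ranksumCompare(numeric(0), 1), "non-empty")
})
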