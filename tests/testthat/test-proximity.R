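test_that("TSS windows are strand-aware, clipped and deduplicated", {
  gi <- GenomeIndex("chr1", 20000)
  ## plus-strand gene [5000,8000) in 0-based terms -> GRanges [5001,8000]
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(5001, 5001), c(8000, 8000)),
    strand = c("+", "-"))
  S4Vectors::mcols(genes)$gene_id <- c("gp", "gm")
  w <- buildTssWindows(genes, 3000, gi)
  ## plus: TSS 5000 (0-based), window [2000, 8000]
  expect_equal(S4Vectors::mcols(w)$tss[1], 5000)
  expect_equal(GenomicRanges::start(w)[1] - 1, 2000)
  expect_equal(GenomicRanges::end(w)[1] - 1, 8000)
  ## minus: TSS 7999, window [4999, 10999]
  expect_equal(S4Vectors::mcols(w)$tss[2], 7999)
  expect_equal(GenomicRanges::start(w)[2] - 1, 4999)
  expect_equal(GenomicRanges::end(w)[2] - 1, 10999)

  ## clipping at the chromosome start
  tss <- data.frame(gene_id = "g", chrom = "chr1", tss = 1000,
                    strand = "+")
  wc <- buildTssWindows(tss, 3000, gi)
  expect_equal(GenomicRanges::start(wc) - 1, 0)
  expect_equal(GenomicRanges::end(wc) - 1, 4000)

  ## identical TSS collapse; missing strand errors
  tss2 <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                     tss = c(1000, 1000), strand = c("+", "+"))
  expect_length(buildTssWindows(tss2, 3000, gi), 1)
  tss3 <- data.frame(gene_id = "z", chrom = "chr1", tss = 5,
                     strand = NA)
  expect_error(buildTssWindows(tss3, 3000, gi), "z")
})

test_that("midpoint overlap counting is inclusive and deduplicated", {
  gi <- GenomeIndex("chr1", 1e6)
  win <- buildTssWindows(data.frame(gene_id = "g", chrom = "chr1",
    tss = 3500, strand = "+"), 3000, gi)  # [500, 6500]
  hs <- function(s0, e0)
    GenomicRanges::GRanges("chr1", IRanges::IRanges(s0 + 1, e0))
  ## hotspot [990,1010): midpoint 1000 inside
  expect_equal(countMidpointOverlaps(hs(990, 1010), win), 1L)
  ## midpoint exactly at tss + 3000 = 6500 counts (inclusive)
  expect_equal(countMidpointOverlaps(hs(6450, 6551), win), 1L)
  ## midpoint at 6501: outside
  expect_equal(countMidpointOverlaps(hs(6452, 6551), win), 0L)
  ## two windows containing one midpoint contribute 1
  win2 <- c(win, buildTssWindows(data.frame(gene_id = "h",
    chrom = "chr1", tss = 2000, strand = "+"), 3000, gi))
  expect_equal(countMidpointOverlaps(hs(990, 1010), win2), 1L)
  expect_equal(countMidpointOverlaps(GenomicRanges::GRanges(), win), 0L)
})

test_that("midpoint counting is invariant to splitting windows", {
  gi <- GenomeIndex("chr1", 1e5)
  whole <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2001, 8000))
  parts <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(2001, 4001, 6001), c(4000, 6000, 8000)))
  set.seed(9)
  s0 <- sample(0:9e4, 200)
  hsAll <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(s0 + 1, s0 + 500))
  expect_equal(countMidpointOverlaps(hsAll, whole),
               countMidpointOverlaps(hsAll, parts))
})

test_that("random-point null test reports direction and both p-values", {
  gi <- GenomeIndex("chr1", 1e4)
  ## saturated coverage: every null count = nPoints, observed = nPoints
  full <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1e4))
  S4Vectors::mcols(full)$gene_id <- "g"; S4Vectors::mcols(full)$tss <- 0
  res <- randomPointNullTest(5, 5, full, gi, nSets = 50, seed = 2)
  expect_equal(res$direction, "none")
  expect_equal(res$empiricalP, 1)
  expect_equal(res$tTestP, 1)

  ## zero-variance null with a different observed value
  res0 <- randomPointNullTest(5, 3, full, gi, nSets = 50, seed = 2)
  expect_equal(res0$tTestP, 0)
  expect_equal(res0$empiricalP, 1 / 51)
  expect_equal(res0$direction, "depleted")
})

test_that("null counts match the coverage expectation", {
  gi <- GenomeIndex("chr1", 1e5)
  win <- buildTssWindows(data.frame(gene_id = c("a", "b"),
    chrom = "chr1", tss = c(2e4, 6e4), strand = "+"), 3000, gi)
  covered <- sum(GenomicRanges::width(GenomicRanges::reduce(win)))
  res <- randomPointNullTest(50, 10, win, gi, nSets = 400, seed = 6)
  expect0 <- 50 * covered / 1e5
  se <- sqrt(50 * (covered / 1e5) * (1 - covered / 1e5) / 400)
  expect_lt(abs(res$nullMean - expect0), 3 * se)
})

test_that("empirical p from the null test is valid under the null", {
  ## hotspots placed by the same uniform process as the null points. The
  ## reported p is one-sided in the observed direction (chosen post hoc),
  ## so its null rejection rate is bounded by 2a, not a
  gi <- GenomeIndex("chr1", 5e4)
  win <- buildTssWindows(data.frame(gene_id = letters[1:3],
    chrom = "chr1", tss = c(1e4, 2.5e4, 4e4), strand = "+"), 2000, gi)
  set.seed(77)
  ps <- vapply(1:400, function(k) {
    pts0 <- sample(0:(5e4 - 1), 20, replace = TRUE)
    obs <- countMidpointOverlaps(GenomicRanges::GRanges("chr1",
      IRanges::IRanges(pts0 + 1, pts0 + 1)), win)
    randomPointNullTest(20, obs, win, gi, nSets = 99,
                        seed = k)$empiricalP
  }, numeric(1))
  for (a in c(0.01, 0.05, 0.1, 0.25)) {
    expect_lte(mean(ps <= a), 2 * a + 3 * sqrt(2 * a * (1 - 2 * a) / 400))
  }
  ## and the p-values are not degenerate at 1
  expect_gt(mean(ps <= 0.5), 0.2)
})

test_that("any-overlap statistics use half-open-consistent arithmetic", {
  a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
  b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 200))
  ## 0-based [0,100) and [99,200): 1 bp overlap
  s <- intervalOverlapStats(a, b)
  expect_equal(s$nAOverlapping, 1L)
  expect_equal(s$fractionA, 1)
  ident <- intervalOverlapStats(a, a)
  expect_equal(ident$fractionA, 1)
  expect_equal(ident$fractionB, 1)
  disj <- intervalOverlapStats(a,
    GenomicRanges::GRanges("chr1", IRanges::IRanges(500, 600)))
  expect_equal(disj$nAOverlapping, 0L)
  expect_equal(disj$fractionA, 0)
})

test_that("hotspot-TSS tables report distances and overlapped genes", {
  gi <- GenomeIndex("chr1", 1e5)
  win <- buildTssWindows(data.frame(gene_id = c("a", "b"),
    chrom = "chr1", tss = c(1e4, 1.2e4), strand = "+"), 3000, gi)
  hot <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(10500, 50001), c(11500, 50100)))
  tab <- hotspotTssTable(hot, win)
  expect_equal(tab$overlappedGenes[1], "a,b")
  expect_equal(tab$overlappedGenes[2], "")
  expect_equal(tab$nearestGene[1], "a")
  expect_gt(tab$distanceToTss[2], 3000)
})
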