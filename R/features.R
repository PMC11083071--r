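## interval_features module: GC content and nucleotide diversity of
## interval sets, size-matched random-interval nulls, and the significance
## machinery (empirical p, rank-sum comparison).

#' GC content of intervals
#'
#' GC fraction `(G + C) / (A + C + G + T)` per interval, case-insensitive;
#' ambiguous bases are excluded from the denominator, and an interval with
#' no unambiguous base is `NA`.
#'
#' @param fasta a [Biostrings::DNAStringSet] (names = chromosomes) or a
#'   FASTA path.
#' @param intervals a `GRanges` (1-based closed).
#' @return numeric vector of GC fractions, one per interval.
#' @examples
#' dss <- Biostrings::DNAStringSet(c(chr1 = "ATATGCGC"))
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, c(4, 8)))
#' gcOfIntervals(dss, gr)
#' @export
gcOfIntervals <- function(fasta, intervals) {
  dss <- if (is.character(fasta)) Biostrings::readDNAStringSet(fasta) else
    fasta
  ch <- as.character(GenomeInfoDb::seqnames(intervals))
  if (!all(ch %in% names(dss)))
    stop("intervals on chromosomes absent from the FASTA: ",
         paste(unique(setdiff(ch, names(dss))), collapse = ", "))
  s <- GenomicRanges::start(intervals); e <- GenomicRanges::end(intervals)
  if (any(s < 1) || any(e > Biostrings::width(dss)[match(ch, names(dss))]))
    stop("interval beyond sequence end")
  vapply(seq_along(intervals), function(i) {
    sub <- Biostrings::subseq(dss[[ch[i]]], s[i], e[i])
    f <- Biostrings::alphabetFrequency(sub)
    denom <- sum(f[c("A", "C", "G", "T")])
    if (denom == 0) return(NA_real_)
    sum(f[c("G", "C")]) / denom
  }, numeric(1))
}

#' Nucleotide diversity (pi) of intervals
#'
#' Per-site diversity is `2 j (n - j) / (n (n - 1))` with `n` the
#' non-missing haplotype count and `j` the alternate-haplotype count (the
#' mean pairwise difference at the site). Interval pi is the sum of site
#' values over sites inside the interval divided by the interval length in
#' bp; monomorphic positions contribute zero. Sites with fewer than 2
#' haplotypes are skipped and counted in the `"skipped"` attribute.
#'
#' @param x a [VariantTable-class]; the haplotype matrix is used when
#'   present, else genotypes contribute two haplotypes each (alt dosage).
#' @param intervals a `GRanges` (1-based closed).
#' @return numeric vector of per-bp diversity values, one per interval.
#' @examples
#' sites <- data.frame(chrom = "chr1", pos = 50, ref = "A", alt = "G",
#'                     qual = 100, depth = NA)
#' hap <- matrix(c(1L, 1L, 0L, 0L), 1)
#' piOfIntervals(VariantTable(sites, haplotypes = hap),
#'               GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100)))
#' @export
piOfIntervals <- function(x, intervals) {
  sites <- variantSites(x)
  if (ncol(x@haplotypes)) {
    n <- rowSums(!is.na(x@haplotypes))
    j <- rowSums(x@haplotypes == 1L, na.rm = TRUE)
  } else {
    n <- 2 * rowSums(!is.na(x@geno))
    j <- rowSums(x@geno, na.rm = TRUE)
  }
  skip <- n < 2
  sitePi <- ifelse(skip, 0, 2 * j * (n - j) / (n * pmax(n - 1, 1)))
  gr <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$pos, sites$pos))
  hits <- GenomicRanges::findOverlaps(gr, intervals)
  out <- numeric(length(intervals))
  agg <- tapply(sitePi[S4Vectors::queryHits(hits)],
                S4Vectors::subjectHits(hits), sum)
  out[as.integer(names(agg))] <- agg
  out <- out / GenomicRanges::width(intervals)
  attr(out, "skipped") <- sum(skip & IRanges::overlapsAny(gr, intervals))
  out
}

#' Feature table of interval sets
#'
#' Convenience wrapper producing the per-interval feature table (GC,
#' pi, length, class) for hotspots, coldspots or random fragments.
#'
#' @param fasta sequences (see [gcOfIntervals()]).
#' @param variants a [VariantTable-class] (see [piOfIntervals()]).
#' @param intervals a `GRanges`.
#' @param class class label for these intervals.
#' @return data.frame: `chrom`, `start` (0-based), `end`, `class`, `gc`,
#'   `pi`, `length`.
#' @export
featureTable <- function(fasta, variants, intervals, class = "interval") {
  bed <- bed0FromGr(intervals)
  data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
             class = class,
             gc = gcOfIntervals(fasta, intervals),
             pi = piOfIntervals(variants, intervals),
             length = GenomicRanges::width(intervals))
}

#' Sample sets of size-matched random intervals
#'
#' Each null set contains one interval per requested size, with exactly
#' that size, placed uniformly over all valid start positions of the
#' genome (every position where the fragment fits on a chromosome
#' without touching the exclusion mask has equal probability). A size
#' with no valid placement raises an error.
#'
#' @param genome a [GenomeIndex-class].
#' @param sizes integer vector of fragment sizes (bp), usually the widths
#'   of the observed interval set.
#' @param nSets number of null sets (default 1000).
#' @param seed integer seed.
#' @param exclude optional `GRanges` mask that fragments must not overlap.
#' @return list of `nSets` `GRanges` objects.
#' @export
sampleMatchedRandomIntervals <- function(genome, sizes, nSets = 1000L,
                                         seed = 1L, exclude = NULL) {
  lens <- chromLengths(genome)
  if (any(sizes > max(lens)))
    stop("size ", max(sizes), " exceeds every chromosome")
  ## mask-free gaps per chromosome, 0-based half-open
  gaps <- lapply(names(lens), function(ch) {
    if (is.null(exclude) || !length(exclude))
      return(data.frame(start = 0, end = lens[[ch]]))
    m <- GenomicRanges::reduce(exclude[GenomeInfoDb::seqnames(exclude) ==
                                         ch])
    free <- GenomicRanges::gaps(m,
      start = 1L, end = as.integer(lens[[ch]]))
    free <- free[GenomicRanges::strand(free) == "*"]
    data.frame(start = GenomicRanges::start(free) - 1,
               end = GenomicRanges::end(free))
  })
  names(gaps) <- names(lens)
  ## for one size: table of (chrom, gapStart, #valid starts in that gap)
  slotsFor <- function(size) {
    out <- do.call(rbind, lapply(names(gaps), function(ch) {
      g <- gaps[[ch]]
      if (!nrow(g)) return(NULL)
      n <- pmax(g$end - g$start - size + 1, 0)
      data.frame(chrom = ch, start = g$start, n = n)[n > 0, ,
                                                     drop = FALSE]
    }))
    if (is.null(out) || !nrow(out))
      stop("no valid placement for a fragment of size ", size,
           " outside the exclusion mask")
    out$cum <- cumsum(out$n)
    out
  }
  slotTabs <- lapply(unique(sizes), slotsFor)
  names(slotTabs) <- as.character(unique(sizes))
  withSeed(seed, {
    lapply(seq_len(nSets), function(s) {
      starts <- numeric(length(sizes)); chs <- character(length(sizes))
      for (i in seq_along(sizes)) {
        tab <- slotTabs[[as.character(sizes[i])]]
        u <- ceiling(runif(1, 0, tab$cum[nrow(tab)]))
        row <- which(tab$cum >= u)[1]
        offset <- u - (if (row == 1) 0 else tab$cum[row - 1]) - 1
        starts[i] <- tab$start[row] + offset
        chs[i] <- tab$chrom[row]
      }
      grFromBed0(chs, starts, starts + sizes)
    })
  })
}

#' Empirical p-value against a permutation null
#'
#' Uses the add-one convention `p = (#{null >= observed} + 1) /
#' (nSets + 1)` for the upper tail (symmetric for the lower tail), which
#' never returns zero; the two-sided value is twice the smaller tail,
#' capped at 1.
#'
#' @param observed observed statistic.
#' @param null numeric vector of null statistics.
#' @param tail `"upper"`, `"lower"` or `"two-sided"`.
#' @return p-value in (0, 1].
#' @examples
#' empiricalP(10, rnorm(999), "upper")  # 1/1000
#' @export
empiricalP <- function(observed, null,
                       tail = c("upper", "lower", "two-sided")) {
  tail <- match.arg(tail)
  n <- length(null)
  up <- (sum(null >= observed) + 1) / (n + 1)
  lo <- (sum(null <= observed) + 1) / (n + 1)
  switch(tail, upper = up, lower = lo,
         `two-sided` = min(1, 2 * min(up, lo)))
}

#' Wilcoxon rank-sum comparison of two feature columns
#'
#' Two-sided Mann-Whitney test for independent samples. Small untied
#' samples use the exact distribution; otherwise the normal approximation
#' with tie correction applies (the [stats::wilcox.test()] switch). Fully
#' tied data return p = 1.
#'
#' @param a,b numeric vectors (non-empty; `NA` dropped).
#' @return list: `U` (Mann-Whitney statistic for `a`), `p`.
#' @export
ranksumCompare <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  if (length(unique(c(a, b))) == 1L)
    return(list(U = length(a) * length(b) / 2, p = 1))
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value)
}
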