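## proximity_tests module: TSS-proximity test for hotspots (midpoint rule
## plus random-point permutation null) and generic interval overlap
## accounting.

#' Build TSS flank windows
#'
#' One window per gene spanning `flank` bp on each side of the
#' transcription start site (the strand-aware 5' end), clipped at
#' chromosome bounds; genes sharing an identical TSS collapse to one
#' window.
#'
#' @param tss TSS table as returned by [readTss()] (`gene_id`, `chrom`,
#'   `tss` 0-based bp, `strand`), or a `GRanges` of gene bodies with
#'   strand, from which the TSS is extracted.
#' @param flank flank size in bp (default 3000, i.e. 6 kb windows).
#' @param genome a [GenomeIndex-class] used for clipping.
#' @return a `GRanges` of windows (1-based closed, inclusive bounds) with
#'   metadata columns `gene_id` and `tss` (0-based).
#' @export
buildTssWindows <- function(tss, flank = 3000, genome) {
  if (is(tss, "GRanges")) {
    strand <- as.character(GenomicRanges::strand(tss))
    if (any(strand == "*")) {
      ids <- if (!is.null(tss$gene_id)) tss$gene_id else seq_along(tss)
      stop("genes without strand: ",
           paste(head(ids[strand == "*"]), collapse = ", "))
    }
    tss0 <- ifelse(strand == "+", GenomicRanges::start(tss) - 1L,
                   GenomicRanges::end(tss) - 1L)
    tss <- data.frame(
      gene_id = if (!is.null(tss$gene_id)) tss$gene_id else
        sprintf("gene%05d", seq_along(tss)),
      chrom = as.character(GenomeInfoDb::seqnames(tss)),
      tss = tss0, strand = strand)
  }
  if (any(is.na(tss$strand) | !tss$strand %in% c("+", "-")))
    stop("genes without strand: ",
         paste(head(tss$gene_id[!tss$strand %in% c("+", "-")]),
               collapse = ", "))
  dup <- duplicated(paste(tss$chrom, tss$tss))
  tss <- tss[!dup, , drop = FALSE]
  lens <- chromLengths(genome)
  if (!all(tss$chrom %in% names(lens)))
    stop("TSS on unknown chromosome")
  maxEnd <- lens[tss$chrom]
  ## 0-based window [tss - flank, tss + flank], clipped; stored 1-based
  start1 <- pmax(tss$tss - flank, 0) + 1
  end1 <- pmin(tss$tss + flank, maxEnd - 1) + 1
  gr <- GenomicRanges::GRanges(tss$chrom, IRanges::IRanges(start1, end1),
                               strand = tss$strand)
  S4Vectors::mcols(gr)$gene_id <- tss$gene_id
  S4Vectors::mcols(gr)$tss <- tss$tss
  gr
}

#' Count hotspots whose midpoint falls in a TSS window
#'
#' The midpoint of an interval is the floor of the mean of its 0-based
#' half-open bounds. A hotspot is counted (once) when its midpoint lies
#' within at least one TSS window; window bounds are inclusive.
#'
#' @param hotspots a `GRanges` of hotspot calls.
#' @param tssWindows a `GRanges` from [buildTssWindows()].
#' @return integer count.
#' @export
countMidpointOverlaps <- function(hotspots, tssWindows) {
  if (!length(hotspots)) return(0L)
  mids <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(hotspots),
    IRanges::IRanges(midpoint1(hotspots), midpoint1(hotspots)))
  sum(IRanges::overlapsAny(mids, tssWindows, ignore.strand = TRUE))
}

#' Random-point permutation test for TSS proximity
#'
#' Builds `nSets` null datasets of `nPoints` genome-wide uniform positions
#' (chromosomes weighted by length), counts how many fall inside the TSS
#' windows in each, and compares the observed hotspot-midpoint count
#' against that null: the empirical p-value uses the tail matching the
#' observed direction (depleted when the observed count is below the null
#' mean), and a one-sample t-test of the null values against the observed
#' count is reported alongside for comparability with permutation-density
#' plots.
#'
#' @param nPoints points per null set (use the observed hotspot count so
#'   observed and null counts are on the same scale).
#' @param observed observed count (e.g. [countMidpointOverlaps()]).
#' @param tssWindows a `GRanges` from [buildTssWindows()].
#' @param genome a [GenomeIndex-class].
#' @param nSets number of null sets (default 1000).
#' @param seed integer seed.
#' @param exclude optional `GRanges`; null points avoid these regions
#'   (e.g. assembly gaps).
#' @return list: `observed`, `nullValues`, `nullMean`, `nullSd`,
#'   `empiricalP`, `tTestP`, `direction` (`"enriched"`, `"depleted"` or
#'   `"none"`).
#' @export
randomPointNullTest <- function(nPoints, observed, tssWindows, genome,
                                nSets = 1000L, seed = 1L, exclude = NULL) {
  if (nPoints < 1L) stop("nPoints must be >= 1")
  lens <- chromLengths(genome)
  nullValues <- withSeed(seed, {
    vapply(seq_len(nSets), function(s) {
      ch <- sample(names(lens), nPoints, replace = TRUE, prob = lens)
      pos0 <- floor(runif(nPoints, 0, lens[ch]))
      if (!is.null(exclude) && length(exclude)) {
        for (tries in seq_len(100L)) {
          pts <- grFromBed0(ch, pos0, pos0 + 1)
          bad <- IRanges::overlapsAny(pts, exclude)
          if (!any(bad)) break
          ch[bad] <- sample(names(lens), sum(bad), replace = TRUE,
                            prob = lens)
          pos0[bad] <- floor(runif(sum(bad), 0, lens[ch[bad]]))
        }
      }
      pts <- GenomicRanges::GRanges(ch, IRanges::IRanges(pos0 + 1,
                                                         pos0 + 1))
      sum(IRanges::overlapsAny(pts, tssWindows, ignore.strand = TRUE))
    }, numeric(1))
  })
  nullMean <- mean(nullValues); nullSd <- sd(nullValues)
  direction <- if (observed < nullMean) "depleted" else
    if (observed > nullMean) "enriched" else "none"
  tail <- switch(direction, depleted = "lower", enriched = "upper",
                 none = "two-sided")
  ep <- empiricalP(observed, nullValues, tail)
  tp <- if (nullSd == 0) {
    if (observed == nullMean) 1 else 0
  } else {
    t.test(nullValues, mu = observed)$p.value
  }
  list(observed = observed, nullValues = nullValues, nullMean = nullMean,
       nullSd = nullSd, empiricalP = ep, tTestP = tp,
       direction = direction)
}

#' Any-overlap statistics between two interval sets
#'
#' Counts intervals of each set overlapping the other by at least 1 bp.
#'
#' @param a,b `GRanges` on the same genome.
#' @return list: `nAOverlapping`, `fractionA`, `nBOverlapping`,
#'   `fractionB`.
#' @export
intervalOverlapStats <- function(a, b) {
  na <- sum(IRanges::overlapsAny(a, b, ignore.strand = TRUE))
  nb <- sum(IRanges::overlapsAny(b, a, ignore.strand = TRUE))
  list(nAOverlapping = na,
       fractionA = if (length(a)) na / length(a) else 0,
       nBOverlapping = nb,
       fractionB = if (length(b)) nb / length(b) else 0)
}

#' Nearest-TSS table for hotspot calls
#'
#' For each hotspot, the distance from its midpoint to the nearest TSS
#' and the gene ids whose windows contain the midpoint.
#'
#' @param hotspots a `GRanges`.
#' @param tssWindows a `GRanges` from [buildTssWindows()].
#' @return data.frame: `chrom`, `start`, `end` (0-based half-open),
#'   `midpoint`, `nearestGene`, `distanceToTss`, `overlappedGenes`.
#' @export
hotspotTssTable <- function(hotspots, tssWindows) {
  bed <- bed0FromGr(hotspots)
  mid1 <- midpoint1(hotspots)
  mids <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(hotspots),
                                 IRanges::IRanges(mid1, mid1))
  tssPts <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(tssWindows),
    IRanges::IRanges(S4Vectors::mcols(tssWindows)$tss + 1,
                     S4Vectors::mcols(tssWindows)$tss + 1))
  nn <- GenomicRanges::distanceToNearest(mids, tssPts,
                                         ignore.strand = TRUE)
  dist <- rep(NA_real_, length(hotspots))
  gene <- rep(NA_character_, length(hotspots))
  dist[S4Vectors::queryHits(nn)] <- S4Vectors::mcols(nn)$distance
  gene[S4Vectors::queryHits(nn)] <-
    S4Vectors::mcols(tssWindows)$gene_id[S4Vectors::subjectHits(nn)]
  ov <- GenomicRanges::findOverlaps(mids, tssWindows,
                                    ignore.strand = TRUE)
  hit <- tapply(
    S4Vectors::mcols(tssWindows)$gene_id[S4Vectors::subjectHits(ov)],
    S4Vectors::queryHits(ov), paste, collapse = ",")
  genes <- rep("", length(hotspots))
  genes[as.integer(names(hit))] <- hit
  data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
             midpoint = mid1 - 1, nearestGene = gene,
             distanceToTss = dist, overlappedGenes = genes)
}
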