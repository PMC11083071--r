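## hotspot_caller module: fold-over-chromosomal-mean filtering of a
## fine-scale map into recombination hotspots and coldspots.

## maximal runs of TRUE in a logical vector -> list of (from, to) interval
## index pairs
trueRuns <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(from = starts[keep], to = ends[keep])
}

#' Call recombination hotspots from a fine-scale map
#'
#' Three-stage filter on inter-SNP interval rates. (1) Candidates are
#' maximal runs of consecutive intervals whose rate strictly exceeds
#' `fold` times the chromosomal mean rate; a candidate spans from the
#' first to the last SNP of its run. (2) Candidates spanning fewer than
#' `minSnps` SNPs or longer than `maxLen` bp are discarded. (3) Surviving
#' candidates separated by at most `mergeMaxSnps` intervening SNPs and a
#' gap of at most `mergeMaxGap` bp are merged, transitively; merged calls
#' may exceed `maxLen` and record how many candidates they absorbed.
#'
#' @param map a [FineScaleMap-class].
#' @param fold rate multiplier over the chromosomal mean (default 10;
#'   strictly greater-than).
#' @param minSnps minimum SNPs a candidate must span (default 2).
#' @param maxLen maximum candidate span in bp before merging
#'   (default 5000).
#' @param mergeMaxSnps,mergeMaxGap merge rule thresholds (defaults 2 SNPs,
#'   1000 bp).
#' @param weighted use the length-weighted chromosomal mean (default);
#'   see [chromosomeMeanRate()].
#' @return a `GRanges` (1-based closed; spans from first to last SNP of
#'   each call) with metadata columns `nSnps`, `meanRate`, `foldOverMean`,
#'   `mergedFrom`. Empty map regions give an empty result.
#' @examples
#' fsm <- FineScaleMap("chr1", c(0, 1000, 1100, 1200, 2200, 10000),
#'                     c(0.001, 0.5, 0.5, 0.001, 0.001))
#' callHotspots(fsm)
#' @export
callHotspots <- function(map, fold = 10, minSnps = 2L, maxLen = 5000,
                         mergeMaxSnps = 2L, mergeMaxGap = 1000,
                         weighted = TRUE) {
  pos <- snpPositions(map)
  rates <- intervalRates(map)
  emptyGr <- GenomicRanges::GRanges()
  if (!length(rates)) return(emptyGr)
  thr <- fold * chromosomeMeanRate(map, weighted = weighted)
  runs <- trueRuns(rates > thr)
  if (!nrow(runs)) return(emptyGr)
  ## candidate spans: SNP index from to to+1
  cand <- data.frame(firstSnp = runs$from, lastSnp = runs$to + 1L)
  cand$start <- pos[cand$firstSnp]
  cand$end <- pos[cand$lastSnp]
  cand$nSnps <- cand$lastSnp - cand$firstSnp + 1L
  ## stage 2: discard short-SNP or over-long candidates
  cand <- cand[cand$nSnps >= minSnps & (cand$end - cand$start) <= maxLen, ,
               drop = FALSE]
  if (!nrow(cand)) return(emptyGr)
  ## stage 3: transitive merging of close neighbours
  groups <- integer(nrow(cand))
  g <- 1L
  groups[1] <- g
  for (i in seq_len(nrow(cand))[-1]) {
    interSnps <- cand$firstSnp[i] - cand$lastSnp[i - 1] - 1L
    gap <- cand$start[i] - cand$end[i - 1]
    if (interSnps <= mergeMaxSnps && gap <= mergeMaxGap) {
      groups[i] <- g
    } else {
      g <- g + 1L
      groups[i] <- g
    }
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(cand)), groups),
    function(ii) {
      firstSnp <- cand$firstSnp[ii[1]]
      lastSnp <- cand$lastSnp[ii[length(ii)]]
      iv <- firstSnp:(lastSnp - 1L)  # all intervals inside the span
      len <- diff(pos[firstSnp:lastSnp])
      mr <- sum(rates[iv] * len) / sum(len)
      data.frame(start = pos[firstSnp], end = pos[lastSnp],
                 nSnps = lastSnp - firstSnp + 1L, meanRate = mr,
                 mergedFrom = length(ii))
    }))
  gr <- grFromBed0(map@chrom, out$start, out$end + 1)
  S4Vectors::mcols(gr)$nSnps <- out$nSnps
  S4Vectors::mcols(gr)$meanRate <- out$meanRate
  S4Vectors::mcols(gr)$foldOverMean <- out$meanRate * fold / thr
  S4Vectors::mcols(gr)$mergedFrom <- out$mergedFrom
  sort(gr)
}

#' Call recombination coldspots from a fine-scale map
#'
#' Maximal runs of consecutive intervals whose rate is strictly below
#' `fold` times the chromosomal mean, spanning at least `minSnps` SNPs.
#' No length cap and no merging are applied.
#'
#' @inheritParams callHotspots
#' @param fold fraction of the chromosomal mean (default 0.1; strictly
#'   less-than).
#' @param minSnps minimum SNPs per call (default 3).
#' @return a `GRanges` with metadata columns `nSnps`, `meanRate`.
#' @export
callColdspots <- function(map, fold = 0.1, minSnps = 3L, weighted = TRUE) {
  pos <- snpPositions(map)
  rates <- intervalRates(map)
  emptyGr <- GenomicRanges::GRanges()
  if (!length(rates)) return(emptyGr)
  thr <- fold * chromosomeMeanRate(map, weighted = weighted)
  runs <- trueRuns(rates < thr)
  if (!nrow(runs)) return(emptyGr)
  cand <- data.frame(firstSnp = runs$from, lastSnp = runs$to + 1L)
  cand$nSnps <- cand$lastSnp - cand$firstSnp + 1L
  cand <- cand[cand$nSnps >= minSnps, , drop = FALSE]
  if (!nrow(cand)) return(emptyGr)
  mr <- vapply(seq_len(nrow(cand)), function(i) {
    iv <- cand$firstSnp[i]:(cand$lastSnp[i] - 1L)
    len <- diff(pos[cand$firstSnp[i]:cand$lastSnp[i]])
    sum(rates[iv] * len) / sum(len)
  }, numeric(1))
  gr <- grFromBed0(map@chrom, pos[cand$firstSnp], pos[cand$lastSnp] + 1)
  S4Vectors::mcols(gr)$nSnps <- cand$nSnps
  S4Vectors::mcols(gr)$meanRate <- mr
  sort(gr)
}

#' Score interval calls against a planted truth
#'
#' A planted interval is recovered when some call reciprocally overlaps it
#' by at least `minReciprocalOverlap` (the overlap must cover that
#' fraction of both intervals). Sensitivity is the fraction of planted
#' intervals recovered; precision is the fraction of calls matching some
#' planted interval.
#'
#' @param calls,truth `GRanges` on the same genome.
#' @param minReciprocalOverlap fraction in (0, 1] (default 0.5).
#' @return list: `sensitivity`, `precision` (each `NA` when its
#'   denominator is empty), `nRecovered`, `nMatchedCalls`.
#' @export
recoveryScore <- function(calls, truth, minReciprocalOverlap = 0.5) {
  if (!length(truth))
    return(list(sensitivity = NA_real_,
                precision = if (length(calls)) 0 else NA_real_,
                nRecovered = 0L, nMatchedCalls = 0L))
  if (!length(calls))
    return(list(sensitivity = 0, precision = NA_real_,
                nRecovered = 0L, nMatchedCalls = 0L))
  hits <- GenomicRanges::findOverlaps(calls, truth)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(IRanges::pintersect(
    IRanges::ranges(calls)[qh], IRanges::ranges(truth)[sh]))
  recip <- ov >= minReciprocalOverlap * GenomicRanges::width(calls)[qh] &
           ov >= minReciprocalOverlap * GenomicRanges::width(truth)[sh]
  list(sensitivity = length(unique(sh[recip])) / length(truth),
       precision = length(unique(qh[recip])) / length(calls),
       nRecovered = length(unique(sh[recip])),
       nMatchedCalls = length(unique(qh[recip])))
}

#' Summarize hotspot/coldspot calls
#'
#' @param gr a `GRanges` of calls.
#' @return data.frame: per-chromosome `n`, `meanLength`, plus a `TOTAL`
#'   row.
#' @export
summarizeCalls <- function(gr) {
  if (!length(gr))
    return(data.frame(chrom = "TOTAL", n = 0L, meanLength = NA_real_))
  ch <- as.character(GenomeInfoDb::seqnames(gr))
  w <- GenomicRanges::width(gr)
  per <- aggregate(w, list(chrom = ch), function(v)
    c(n = length(v), meanLength = mean(v)))
  out <- data.frame(chrom = per$chrom, n = as.integer(per$x[, "n"]),
                    meanLength = per$x[, "meanLength"])
  rbind(out, data.frame(chrom = "TOTAL", n = length(gr),
                        meanLength = mean(w)))
}
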