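# Independent brute-force oracle for hotspot/coldspot calling.
#
# Deliberately written as a literal, loop-based transcription of the filter
# rules, sharing no code with the package implementation:
#   hotspots: (1) maximal runs of intervals with rate strictly > fold*mean;
#   (2) drop runs spanning < minSnps SNPs OR longer than maxLen bp;
#   (3) merge neighbours separated by <= mergeMaxSnps intervening SNPs AND
#   gap <= mergeMaxGap, transitively.
#   coldspots: maximal runs strictly < fold*mean spanning >= minSnps SNPs.
# Returns plain data.frames of 0-based [start, end] SNP-position spans.

oracleMean <- function(pos, rates, weighted = TRUE) {
  if (weighted) {
    len <- diff(pos)
    sum(rates * len) / sum(len)
  } else mean(rates)
}

oracleRuns <- function(flag) {
  runs <- list()
  i <- 1
  while (i <= length(flag)) {
    if (flag[i]) {
      j <- i
      while (j < length(flag) && flag[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  runs
}

oracleHotspots <- function(pos, rates, fold = 10, minSnps = 2,
                           maxLen = 5000, mergeMaxSnps = 2,
                           mergeMaxGap = 1000) {
  thr <- fold * oracleMean(pos, rates)
  runs <- oracleRuns(rates > thr)
  cand <- list()
  for (r in runs) {
    firstSnp <- r[1]; lastSnp <- r[2] + 1
    nSnps <- lastSnp - firstSnp + 1
    span <- pos[lastSnp] - pos[firstSnp]
    if (nSnps >= minSnps && span <= maxLen)
      cand[[length(cand) + 1]] <- c(firstSnp, lastSnp)
  }
  if (!length(cand))
    return(data.frame(start = numeric(0), end = numeric(0),
                      nSnps = integer(0)))
  merged <- list(cand[[1]])
  if (length(cand) > 1) {
    for (k in 2:length(cand)) {
      prev <- merged[[length(merged)]]
      cur <- cand[[k]]
      interSnps <- cur[1] - prev[2] - 1
      gap <- pos[cur[1]] - pos[prev[2]]
      if (interSnps <= mergeMaxSnps && gap <= mergeMaxGap) {
        merged[[length(merged)]] <- c(prev[1], cur[2])
      } else {
        merged[[length(merged) + 1]] <- cur
      }
    }
  }
  data.frame(
    start = vapply(merged, function(m) pos[m[1]], numeric(1)),
    end = vapply(merged, function(m) pos[m[2]], numeric(1)),
    nSnps = vapply(merged, function(m) m[2] - m[1] + 1, numeric(1)))
}

oracleColdspots <- function(pos, rates, fold = 0.1, minSnps = 3) {
  thr <- fold * oracleMean(pos, rates)
  runs <- oracleRuns(rates < thr)
  out <- list()
  for (r in runs) {
    firstSnp <- r[1]; lastSnp <- r[2] + 1
    if (lastSnp - firstSnp + 1 >= minSnps)
      out[[length(out) + 1]] <- c(firstSnp, lastSnp)
  }
  if (!length(out))
    return(data.frame(start = numeric(0), end = numeric(0),
                      nSnps = integer(0)))
  data.frame(
    start = vapply(out, function(m) pos[m[1]], numeric(1)),
    end = vapply(out, function(m) pos[m[2]], numeric(1)),
    nSnps = vapply(out, function(m) m[2] - m[1] + 1, numeric(1)))
}

# random small map with a heavy-tailed rate distribution so extreme runs
# (hot and cold) actually occur
randomSmallMap <- function(maxSnps = 60) {
  n <- sample(3:maxSnps, 1)
  pos <- cumsum(c(0, sample(c(50:2000), n - 1, replace = TRUE)))
  rates <- exp(rnorm(n - 1, 0, 3))
  ## sprinkle exact zeros and ties to exercise the strict inequalities
  if (runif(1) < 0.3) rates[sample(n - 1, 1)] <- 0
  FineScaleMap("chr1", pos, rates)
}

# package calls as comparable data.frames (0-based SNP spans)
callsAsDf <- function(gr) {
  data.frame(start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr) - 1,
             nSnps = S4Vectors::mcols(gr)$nSnps)
}

# brute-force pi oracle: mean pairwise difference per site, summed over
# the interval and divided by its length
bruteForcePi <- function(hap, pos, start1, end1) {
  inIv <- which(pos >= start1 & pos <= end1)
  tot <- 0
  for (s in inIv) {
    al <- hap[s, ]
    al <- al[!is.na(al)]
    if (length(al) < 2) next
    d <- 0; np <- 0
    for (i in seq_len(length(al) - 1)) for (j in (i + 1):length(al)) {
      d <- d + (al[i] != al[j]); np <- np + 1
    }
    tot <- tot + d / np
  }
  tot / (end1 - start1 + 1)
}

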