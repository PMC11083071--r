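## finescale_map module: window aggregation of fine-scale maps and
## correlation comparisons between maps.

#' Aggregate a fine-scale map to fixed windows
#'
#' The window rate is the length-weighted mean of the inter-SNP interval
#' rates clipped to the window: an interval contributes in proportion to
#' its overlap length. Windows with zero covered bp are `NA` (missing),
#' never zero. Aggregation conserves map length exactly:
#' `sum(rate * coveredMb)` over windows equals `sum(rate * lengthMb)` over
#' intervals.
#'
#' @param map a [FineScaleMap-class].
#' @param window window size in bp (default 1 Mb).
#' @param chromLength chromosome length; defaults to the last SNP
#'   position.
#' @return a [WindowMap-class] with metadata columns `rate` and
#'   `covered` (bp of the window covered by map intervals).
#' @examples
#' fsm <- FineScaleMap("chr1", c(0, 5e5, 1e6), c(1, 3))
#' windowRates(aggregateToWindows(fsm, 1e6))
#' @export
aggregateToWindows <- function(map, window = 1e6, chromLength = NULL) {
  if (window <= 0) stop("window must be > 0")
  pos <- snpPositions(map)
  rates <- intervalRates(map)
  if (is.null(chromLength)) chromLength <- pos[length(pos)]
  starts <- seq(0, chromLength - 1, by = window)
  ends <- pmin(starts + window, chromLength)
  nW <- length(starts)
  wsum <- numeric(nW); cov <- numeric(nW)
  istart <- pos[-length(pos)]; iend <- pos[-1]
  for (w in seq_len(nW)) {
    ov <- pmin(iend, ends[w]) - pmax(istart, starts[w])
    ov[ov < 0] <- 0
    cov[w] <- sum(ov)
    wsum[w] <- sum(rates * ov)
  }
  rate <- ifelse(cov > 0, wsum / cov, NA_real_)
  gr <- grFromBed0(map@chrom, starts, ends)
  S4Vectors::mcols(gr)$rate <- rate
  S4Vectors::mcols(gr)$covered <- cov
  WindowMap(gr, sex = "both", nMeioses = 0L)
}

#' Mean chromosomal recombination rate
#'
#' @param map a [FineScaleMap-class].
#' @param weighted length-weighted mean `sum(rate * len) / sum(len)`
#'   (default); otherwise the arithmetic mean of the interval rates.
#' @return numeric scalar.
#' @examples
#' fsm <- FineScaleMap("chr1", c(0, 1000, 1100), c(0.001, 0.5))
#' chromosomeMeanRate(fsm)            # length-weighted
#' chromosomeMeanRate(fsm, weighted = FALSE)
#' @export
chromosomeMeanRate <- function(map, weighted = TRUE) {
  r <- intervalRates(map)
  if (!length(r)) stop("empty map")
  if (weighted) {
    len <- intervalLengths(map)
    sum(r * len) / sum(len)
  } else {
    mean(r)
  }
}

#' Convert population-scaled rates by a scalar (e.g. rho to cM/Mb)
#'
#' The population-scaled rate rho = 4 Ne r can be converted to cM/Mb given
#' an effective population size: `cM/Mb = rho_per_bp / (4 Ne) * 1e8`. This
#' is a plain scalar multiply; correlations in this package are rank-based
#' by default and unit-free.
#'
#' @param map a [FineScaleMap-class].
#' @param factor multiplicative conversion factor.
#' @param units new unit tag.
#' @return a rescaled [FineScaleMap-class].
#' @export
scaleRates <- function(map, factor, units = map@units) {
  FineScaleMap(map@chrom, snpPositions(map), intervalRates(map) * factor,
               units = units, source = map@source)
}

#' Correlation between two windowed maps
#'
#' Computed over the intersecting windows that are non-missing in both
#' maps; at least 3 shared windows are required.
#'
#' @param a,b [WindowMap-class] objects.
#' @param method `"spearman"` (default; the rank correlation) or
#'   `"pearson"`.
#' @return list: `estimate`, `p`, `n`, `method`.
#' @export
mapCorrelation <- function(a, b, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ga <- windowRanges(a); gb <- windowRanges(b)
  keyA <- paste(GenomeInfoDb::seqnames(ga), GenomicRanges::start(ga))
  keyB <- paste(GenomeInfoDb::seqnames(gb), GenomicRanges::start(gb))
  ia <- match(keyB, keyA)
  shared <- which(!is.na(ia))
  ra <- windowRates(a)[ia[shared]]
  rb <- windowRates(b)[shared]
  ok <- !is.na(ra) & !is.na(rb)
  if (sum(ok) < 3L) stop("fewer than 3 shared non-missing windows")
  ct <- suppressWarnings(cor.test(ra[ok], rb[ok], method = method,
                                  exact = FALSE))
  list(estimate = unname(ct$estimate), p = ct$p.value, n = sum(ok),
       method = method)
}

#' Within- versus between-group contrast of map correlations
#'
#' Partitions the off-diagonal entries of a pairwise map-correlation
#' matrix into within-group and between-group coefficients and compares
#' the two sets by a Welch t-test.
#'
#' @param corrMatrix symmetric numeric matrix of pairwise correlation
#'   coefficients (diagonal ignored).
#' @param groups group label per map (row/column).
#' @return list: `withinMean`, `betweenMean`, `t`, `df`, `p`, `nWithin`,
#'   `nBetween`.
#' @export
groupCorrelationContrast <- function(corrMatrix, groups) {
  if (length(unique(groups)) < 2L) stop("need at least 2 groups")
  n <- nrow(corrMatrix)
  within <- numeric(); between <- numeric()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    v <- corrMatrix[i, j]
    if (groups[i] == groups[j]) within <- c(within, v)
    else between <- c(between, v)
  }
  if (length(within) < 2L || length(between) < 1L)
    stop("need >= 2 within-group pairs and >= 1 between-group pair")
  if (stats::var(c(within, between)) == 0) {
    return(list(withinMean = mean(within), betweenMean = mean(between),
                t = 0, df = NA_real_, p = 1,
                nWithin = length(within), nBetween = length(between)))
  }
  tt <- t.test(within, between)
  list(withinMean = mean(within), betweenMean = mean(between),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, nWithin = length(within),
       nBetween = length(between))
}
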