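## Internal helpers shared across modules.

#' Derive a per-stage child seed from a global seed
#'
#' Fans a single pipeline seed out into independent per-stage seeds by a
#' stable string hash, so adding a stage never perturbs the draws of earlier
#' stages. Result is always a valid 32-bit R integer seed.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return integer seed.
#' @export
stageSeed <- function(seed, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 48271 + h) %% 2147483647)
}

## run code under a local RNG state (does not disturb the caller's RNG)
withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

## GRanges constructor from 0-based half-open coordinates
grFromBed0 <- function(chrom, start0, end0, ...) {
  GenomicRanges::GRanges(rep(chrom, length.out = length(start0)),
    IRanges::IRanges(start = start0 + 1, end = end0), ...)
}

## 0-based half-open view of a GRanges, as a data.frame
bed0FromGr <- function(gr) {
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

## midpoint of intervals under the 0-based half-open convention,
## returned 1-based (floor of the mean of start0 and end0)
midpoint1 <- function(gr) {
  floor((GenomicRanges::start(gr) - 1 + GenomicRanges::end(gr)) / 2) + 1
}

## sample n non-overlapping intervals of given widths on [0, chromLength)
## (0-based starts, returned in the caller's width order); uniform over
## non-overlapping arrangements by stick-breaking the free space into
## exponential gaps, with the width-to-slot assignment randomized
placeNonOverlapping <- function(widths, chromLength) {
  n <- length(widths)
  if (!n) return(data.frame(start = numeric(0), end = numeric(0)))
  free <- chromLength - sum(widths)
  if (free <= n)
    stop("planted intervals cannot fit in the chromosome without overlap")
  slot <- sample.int(n)                    # which slot each width occupies
  w <- widths[order(slot)]                 # widths in left-to-right order
  gaps <- rexp(n + 1)
  gaps <- gaps / sum(gaps) * free
  startOrdered <- floor(cumsum(gaps[seq_len(n)]) +
                          cumsum(c(0, w[-n])))
  ## rounding can shave sub-bp gaps to overlap; repair left to right
  for (k in seq_len(n)[-1]) {
    lo <- startOrdered[k - 1] + w[k - 1]
    if (startOrdered[k] < lo) startOrdered[k] <- lo
  }
  start <- numeric(n)
  start[order(slot)] <- startOrdered
  data.frame(start = start, end = start + widths)
}
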