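## motif_enrich module: log-odds PWM scanning of interval sequences and
## the hotspot-versus-coldspot motif enrichment test.

## best log-odds window score of one DNAString on both strands;
## windows containing ambiguous bases are skipped (NA when none valid)
scanOne <- function(seq, loFwd, loRev) {
  m <- nrow(loFwd)
  L <- length(seq)
  if (L < m) return(c(score = NA_real_, offset = NA_real_, strand = NA))
  nOff <- L - m + 1L
  at <- seq_len(nOff)
  sf <- suppressWarnings(
    Biostrings::PWMscoreStartingAt(t(loFwd), seq, starting.at = at))
  sr <- suppressWarnings(
    Biostrings::PWMscoreStartingAt(t(loRev), seq, starting.at = at))
  ## mask windows touching ambiguous letters
  freq <- Biostrings::alphabetFrequency(seq)
  if (sum(freq[c("A", "C", "G", "T")]) < L) {
    lv <- Biostrings::letterFrequencyInSlidingView(seq, m, "ACGT")
    bad <- lv[, 1] < m
    sf[bad] <- NA; sr[bad] <- NA
  }
  if (all(is.na(sf)) && all(is.na(sr)))
    return(c(score = NA_real_, offset = NA_real_, strand = NA))
  bf <- suppressWarnings(max(sf, na.rm = TRUE))
  br <- suppressWarnings(max(sr, na.rm = TRUE))
  if (is.infinite(bf)) bf <- -Inf
  if (is.infinite(br) && br < 0) br <- -Inf
  if (bf >= br) {
    c(score = bf, offset = which.max(replace(sf, is.na(sf), -Inf)),
      strand = 1)
  } else {
    c(score = br, offset = which.max(replace(sr, is.na(sr), -Inf)),
      strand = 2)
  }
}

## forward and reverse-complement log-odds matrices (L x 4)
logOddsPair <- function(pwm) {
  lo <- logOdds(pwm)
  ## reverse complement: reverse positions, swap A<->T and C<->G
  loRev <- lo[rev(seq_len(nrow(lo))), c("T", "G", "C", "A"), drop = FALSE]
  colnames(loRev) <- c("A", "C", "G", "T")
  list(fwd = lo, rev = loRev)
}

#' Maximum log-odds PWM score of a sequence
#'
#' Scans every offset on both strands with the log-odds view of the PWM
#' (see [logOdds()]) and returns the best windowed sum in bits. Windows
#' containing ambiguous bases are skipped; a sequence shorter than the
#' motif, or with no valid window, scores `NA`.
#'
#' @param seq a DNA sequence (character or [Biostrings::DNAString]).
#' @param pwm a [PWM-class].
#' @return numeric score in bits (`NA` when no valid window).
#' @examples
#' m <- matrix(c(0.97, 0.01, 0.01, 0.01), 6, 4, byrow = TRUE,
#'             dimnames = list(NULL, c("A", "C", "G", "T")))
#' maxLogoddsScore("TTTAAAAAATTT", PWM(m))
#' @export
maxLogoddsScore <- function(seq, pwm) {
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  lo <- logOddsPair(pwm)
  unname(scanOne(seq, lo$fwd, lo$rev)["score"])
}

#' Score a set of sequences against a PWM
#'
#' @param seqs a [Biostrings::DNAStringSet] or character vector.
#' @param pwm a [PWM-class].
#' @return data.frame: `id`, `maxScore` (bits; `NA` when no valid
#'   window), `offset` (1-based start of the best window), `strand`.
#' @export
scoreSequences <- function(seqs, pwm) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  lo <- logOddsPair(pwm)
  res <- t(vapply(seq_along(seqs), function(i)
    scanOne(seqs[[i]], lo$fwd, lo$rev), c(score = 0, offset = 0,
                                          strand = 0)))
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("seq%04d", seq_along(seqs))
  data.frame(id = ids, maxScore = res[, "score"],
             offset = res[, "offset"],
             strand = c("+", "-")[res[, "strand"]])
}

#' PWM enrichment test between hotspot and coldspot sequences
#'
#' Scores each sequence by its maximum log-odds window (both strands) and
#' tests whether hotspot sequences score higher than coldspot sequences.
#' `method = "ranksum"` (default) is a one-sided Mann-Whitney test;
#' `method = "fisher"` dichotomizes at `fisherThreshold` (has a window at
#' or above the threshold) and applies a one-sided Fisher exact test for
#' hotspot excess. Sequences without a valid window are excluded and
#' counted.
#'
#' @param hotSeqs,coldSeqs sequence sets ([Biostrings::DNAStringSet] or
#'   character), both non-empty.
#' @param pwm a [PWM-class].
#' @param method `"ranksum"` or `"fisher"`.
#' @param fisherThreshold score threshold (bits) for the Fisher branch;
#'   default half the maximum attainable consensus score.
#' @return list: `method`, `statistic`, `p`, `hotHits`, `coldHits`,
#'   `nHot`, `nCold`, `nExcluded`, `threshold` (Fisher only).
#' @export
pwmEnrichmentTest <- function(hotSeqs, coldSeqs, pwm,
                              method = c("ranksum", "fisher"),
                              fisherThreshold = NULL) {
  method <- match.arg(method)
  if (!length(hotSeqs) || !length(coldSeqs))
    stop("both sequence classes must be non-empty")
  hs <- scoreSequences(hotSeqs, pwm)$maxScore
  cs <- scoreSequences(coldSeqs, pwm)$maxScore
  nExcluded <- sum(is.na(hs)) + sum(is.na(cs))
  hs <- hs[!is.na(hs)]; cs <- cs[!is.na(cs)]
  if (!length(hs) || !length(cs))
    stop("a class has no scorable sequence")
  if (method == "ranksum") {
    if (length(unique(c(hs, cs))) == 1L) {
      return(list(method = method, statistic = length(hs) * length(cs) / 2,
                  p = 1, hotHits = NA_integer_, coldHits = NA_integer_,
                  nHot = length(hs), nCold = length(cs),
                  nExcluded = nExcluded, threshold = NA_real_))
    }
    wt <- suppressWarnings(wilcox.test(hs, cs, alternative = "greater"))
    list(method = method, statistic = unname(wt$statistic),
         p = wt$p.value, hotHits = NA_integer_, coldHits = NA_integer_,
         nHot = length(hs), nCold = length(cs), nExcluded = nExcluded,
         threshold = NA_real_)
  } else {
    if (is.null(fisherThreshold)) {
      lo <- logOdds(pwm)
      fisherThreshold <- sum(apply(lo, 1, max)) / 2
    }
    hotHits <- sum(hs >= fisherThreshold)
    coldHits <- sum(cs >= fisherThreshold)
    tab <- matrix(c(hotHits, length(hs) - hotHits,
                    coldHits, length(cs) - coldHits), 2,
                  dimnames = list(c("hit", "miss"), c("hot", "cold")))
    ft <- fisher.test(tab, alternative = "greater")
    list(method = method, statistic = unname(ft$estimate),
         p = ft$p.value, hotHits = hotHits, coldHits = coldHits,
         nHot = length(hs), nCold = length(cs), nExcluded = nExcluded,
         threshold = fisherThreshold)
  }
}

#' Estimate a PWM background from sequences
#'
#' Base composition of a sequence set, usable as a GC-aware background
#' for [PWM-class] scanning (e.g. estimated from coldspot sequences).
#'
#' @param seqs a [Biostrings::DNAStringSet] or character vector.
#' @return numeric length-4 frequency vector (A, C, G, T).
#' @export
backgroundFromSequences <- function(seqs) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  f <- colSums(Biostrings::alphabetFrequency(seqs)[, c("A", "C", "G", "T"),
                                                   drop = FALSE])
  as.numeric(f / sum(f))
}

#' Extract interval sequences from a genome
#'
#' @param fasta a [Biostrings::DNAStringSet] or FASTA path.
#' @param intervals a `GRanges` (1-based closed).
#' @return a [Biostrings::DNAStringSet], one element per interval.
#' @export
extractIntervalSequences <- function(fasta, intervals) {
  dss <- if (is.character(fasta)) Biostrings::readDNAStringSet(fasta) else
    fasta
  ch <- as.character(GenomeInfoDb::seqnames(intervals))
  out <- Biostrings::DNAStringSet(vapply(seq_along(intervals), function(i)
    as.character(Biostrings::subseq(dss[[ch[i]]],
                                    GenomicRanges::start(intervals)[i],
                                    GenomicRanges::end(intervals)[i])),
    character(1)))
  names(out) <- sprintf("%s:%d-%d", ch,
                        GenomicRanges::start(intervals) - 1,
                        GenomicRanges::end(intervals))
  out
}
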