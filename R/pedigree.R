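## pedigree_recomb module: FID selection, transmission phasing, run-based
## crossover detection, close-double-crossover QC, Monte-Carlo 1 Mb window
## rates and ACM comparisons.

## ---------------------------------------------------------------------------
## FID selection
## ---------------------------------------------------------------------------

#' Select focal individuals (FIDs) from a pedigree
#'
#' An individual qualifies as a focal individual when it has at least one
#' known parent and at least two offspring, or no known parent but at least
#' four offspring.
#'
#' @param ped pedigree data.frame with columns `id`, `sire`, `dam`, `sex`,
#'   `population` (unknown parents `NA`).
#' @return character vector of FID ids (possibly empty).
#' @examples
#' ped <- data.frame(id = c("A", "B", "C", "D"),
#'                   sire = c(NA, "A", "A", NA),
#'                   dam = c(NA, NA, NA, NA),
#'                   sex = c("male", "unknown", "unknown", "female"),
#'                   population = "p")
#' selectFids(ped)  # "A" has no known parent and only 2 offspring
#' @export
selectFids <- function(ped) {
  nOff <- table(c(ped$sire[!is.na(ped$sire)], ped$dam[!is.na(ped$dam)]))
  off <- as.integer(nOff[match(ped$id, names(nOff))])
  off[is.na(off)] <- 0L
  knownParent <- !is.na(ped$sire) | !is.na(ped$dam)
  ped$id[(knownParent & off >= 2L) | (!knownParent & off >= 4L)]
}

## ---------------------------------------------------------------------------
## Transmission phasing
## ---------------------------------------------------------------------------

#' Phase a focal individual by transmission and assign offspring origins
#'
#' At each marker where the FID is heterozygous, the allele the FID
#' transmitted to each offspring is deduced from the offspring and mate
#' genotypes (unambiguous when the mate is homozygous or the offspring
#' genotype forces the transmitted allele). The FID's two haplotypes are
#' then assembled marker-by-marker by majority vote: the labelling at each
#' informative marker is chosen so that the fewest offspring switch
#' haplotype origin relative to the previous informative marker, with ties
#' broken towards no switch for the first offspring carrying data (the
#' labelling at the first informative marker is anchored by the first
#' offspring). Mendelian-inconsistent transmissions are set missing and
#' counted.
#'
#' @param x a [VariantTable-class] with genotypes for the FID, mates and
#'   offspring.
#' @param ped pedigree data.frame.
#' @param fid id of the focal individual (needs >= 2 genotyped offspring).
#' @param maskedRegions optional data.frame (`meiosis`, `chrom`, `start`,
#'   `end`): markers inside a region are treated as missing for that
#'   offspring's meiosis (used on re-detection after QC).
#' @return an object of class `originSequences`: list with `origins`
#'   (markers x offspring matrix over \{1, 2, NA\}), `positions` (0-based
#'   marker bp), `chrom`, `fid`, `offspring`, `sex`, and `mendelErrors`
#'   (count of inconsistent transmissions set missing).
#' @export
phaseByTransmission <- function(x, ped, fid, maskedRegions = NULL) {
  g <- genotypes(x)
  if (!fid %in% colnames(g)) stop("FID ", fid, " not genotyped")
  kids <- ped$id[(!is.na(ped$sire) & ped$sire == fid) |
                 (!is.na(ped$dam) & ped$dam == fid)]
  kids <- kids[kids %in% colnames(g)]
  if (length(kids) < 2L) stop("FID ", fid, " has < 2 genotyped offspring")
  sites <- variantSites(x)
  chrom <- sites$chrom[1]
  pos0 <- sites$pos - 1          # marker positions, 0-based
  fidSex <- ped$sex[match(fid, ped$id)]
  nm <- nrow(sites)

  fg <- g[, fid]
  het <- !is.na(fg) & fg == 1L
  ## transmitted allele per (marker, offspring): 0/1/NA
  trans <- matrix(NA_integer_, nm, length(kids),
                  dimnames = list(NULL, kids))
  mendel <- 0L
  for (k in seq_along(kids)) {
    kid <- kids[k]
    prow <- ped[ped$id == kid, ]
    mate <- if (!is.na(prow$sire) && prow$sire == fid) prow$dam else
      prow$sire
    mg <- if (!is.na(mate) && mate %in% colnames(g)) g[, mate] else
      rep(NA_integer_, nm)
    kg <- g[, kid]
    ## possible mate-transmitted alleles
    mAll0 <- !is.na(mg) & mg == 0L     # mate transmits 0
    mAll1 <- !is.na(mg) & mg == 2L     # mate transmits 1
    a <- rep(NA_integer_, nm)
    ok <- het & !is.na(kg)
    ## mate homozygous: transmitted allele forced
    a[ok & mAll0] <- kg[ok & mAll0]          # a = kid - 0
    a[ok & mAll1] <- kg[ok & mAll1] - 1L
    ## mate het/missing: only extreme offspring genotypes are informative
    amb <- ok & !mAll0 & !mAll1
    a[amb & kg == 0L] <- 0L
    a[amb & kg == 2L] <- 1L
    bad <- !is.na(a) & (a < 0L | a > 1L)
    mendel <- mendel + sum(bad)
    a[bad] <- NA_integer_
    if (!is.null(maskedRegions) && nrow(maskedRegions)) {
      mid <- paste0(fid, "_", kid)
      mr <- maskedRegions[maskedRegions$meiosis == mid &
                          maskedRegions$chrom == chrom, , drop = FALSE]
      for (j in seq_len(nrow(mr)))
        a[pos0 >= mr$start[j] & pos0 <= mr$end[j]] <- NA_integer_
    }
    trans[, k] <- a
  }

  ## assemble FID haplotype labelling by minimum-switch majority vote
  origins <- matrix(NA_integer_, nm, length(kids),
                    dimnames = list(NULL, kids))
  infoMarkers <- which(het & rowSums(!is.na(trans)) > 0)
  lastOrigin <- rep(NA_integer_, length(kids))
  anchored <- FALSE
  for (m in infoMarkers) {
    aRow <- trans[m, ]
    if (!anchored) {
      ## hap1 carries the allele seen in the first offspring with data
      first <- which(!is.na(aRow))[1]
      h1 <- aRow[first]
      anchored <- TRUE
    } else {
      ## candidate labellings: hap1 allele = 0 or = 1
      switches <- function(h1cand) {
        o <- ifelse(aRow == h1cand, 1L, 2L)
        cmp <- !is.na(o) & !is.na(lastOrigin)
        sum(o[cmp] != lastOrigin[cmp])
      }
      s0 <- switches(0L); s1 <- switches(1L)
      if (s0 != s1) {
        h1 <- if (s0 < s1) 0L else 1L
      } else {
        ## tie: keep the first offspring-with-data on its previous origin
        h1 <- NA_integer_
        for (k in seq_along(kids)) {
          if (!is.na(aRow[k]) && !is.na(lastOrigin[k])) {
            h1 <- if (lastOrigin[k] == 1L) aRow[k] else 1L - aRow[k]
            break
          }
        }
        if (is.na(h1)) h1 <- aRow[which(!is.na(aRow))[1]]
      }
    }
    o <- ifelse(aRow == h1, 1L, 2L)
    origins[m, ] <- o
    upd <- !is.na(o)
    lastOrigin[upd] <- o[upd]
  }

  structure(list(origins = origins, positions = pos0, chrom = chrom,
                 fid = fid, offspring = kids, sex = fidSex,
                 mendelErrors = mendel),
            class = "originSequences")
}

#' @export
print.originSequences <- function(x, ...) {
  cat("originSequences | FID", x$fid, "(", x$sex, "),",
      length(x$offspring), "offspring,",
      sum(rowSums(!is.na(x$origins)) > 0), "informative markers\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Crossover detection
## ---------------------------------------------------------------------------

## single origin vector (values 1/2/NA over markers) -> crossover bounds
detectRuns <- function(origin, positions, minSupport) {
  inf <- which(!is.na(origin))
  if (!length(inf)) return(NULL)
  vals <- origin[inf]
  r <- rle(vals)
  ## discard runs shorter than minSupport (isolated flips = likely errors),
  ## then merge adjacent equal runs, repeating until stable
  repeat {
    keep <- r$lengths >= minSupport
    if (all(keep)) break
    vals2 <- rep.int(r$values[keep], r$lengths[keep])
    idx2 <- rep.int(keep, r$lengths)
    inf <- inf[idx2]
    if (!length(inf)) return(NULL)
    r <- rle(vals2)
  }
  if (length(r$lengths) < 2L) return(NULL)
  ends <- cumsum(r$lengths)
  leftIdx <- inf[ends[-length(ends)]]
  rightIdx <- inf[ends[-length(ends)] + 1L]
  data.frame(left = positions[leftIdx], right = positions[rightIdx])
}

#' Detect crossovers from offspring origin sequences
#'
#' A crossover is emitted at each boundary between maximal runs of
#' consistent haplotype origin, provided both flanking runs contain at
#' least `minSupport` consecutive informative markers; shorter runs are
#' treated as genotyping errors and dropped (iteratively, re-merging the
#' flanks). Each event is bounded by the flanking informative markers.
#'
#' @param origin an `originSequences` object from [phaseByTransmission()],
#'   or a plain integer vector of origins (values 1/2/NA) together with
#'   `positions`.
#' @param minSupport minimum informative markers per flanking run
#'   (default 3).
#' @param positions marker positions (bp), only when `origin` is a vector.
#' @return data.frame of crossover events: `meiosis`, `chrom`, `left`,
#'   `right`, `sex` (empty when no event survives).
#' @examples
#' detectCrossovers(c(1, 1, 1, 2, 2, 2), minSupport = 3,
#'                  positions = seq(0, 500, by = 100))
#' @export
detectCrossovers <- function(origin, minSupport = 3L, positions = NULL) {
  empty <- data.frame(meiosis = character(), chrom = character(),
                      left = numeric(), right = numeric(),
                      sex = character())
  if (is.numeric(origin) || is.integer(origin)) {
    ev <- detectRuns(as.integer(origin), positions, minSupport)
    if (is.null(ev)) return(empty)
    return(data.frame(meiosis = "meiosis1", chrom = "chr1",
                      left = ev$left, right = ev$right, sex = "unknown"))
  }
  stopifnot(inherits(origin, "originSequences"))
  out <- list()
  for (k in seq_along(origin$offspring)) {
    ev <- detectRuns(origin$origins[, k], origin$positions, minSupport)
    if (is.null(ev)) next
    out[[length(out) + 1]] <- data.frame(
      meiosis = paste0(origin$fid, "_", origin$offspring[k]),
      chrom = origin$chrom, left = ev$left, right = ev$right,
      sex = origin$sex)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Detect crossovers for all meioses of a set of FIDs
#'
#' Convenience driver: phases every FID by transmission, detects crossovers
#' per offspring and assembles a [MeiosisSet-class] (including
#' zero-crossover meioses).
#'
#' @param x a [VariantTable-class].
#' @param ped pedigree data.frame.
#' @param fids FID ids (default [selectFids()]).
#' @param minSupport passed to [detectCrossovers()].
#' @param maskedRegions passed to [phaseByTransmission()].
#' @return a [MeiosisSet-class].
#' @export
detectMeioses <- function(x, ped, fids = selectFids(ped), minSupport = 3L,
                          maskedRegions = NULL) {
  mei <- list(); co <- list()
  for (fid in fids) {
    os <- phaseByTransmission(x, ped, fid, maskedRegions = maskedRegions)
    mei[[fid]] <- data.frame(
      meiosis = paste0(fid, "_", os$offspring), fid = fid,
      offspring = os$offspring, sex = os$sex,
      population = ped$population[match(fid, ped$id)])
    ev <- detectCrossovers(os, minSupport = minSupport)
    if (nrow(ev)) co[[fid]] <- ev
  }
  MeiosisSet(do.call(rbind, c(mei, list(make.row.names = FALSE))),
             if (length(co)) do.call(rbind, c(co,
               list(make.row.names = FALSE))) else NULL,
             if (is.null(maskedRegions)) NULL else maskedRegions)
}

## ---------------------------------------------------------------------------
## Close-double-crossover QC
## ---------------------------------------------------------------------------

#' Mask close double crossovers
#'
#' Double crossovers closer than `minSep` within one meiosis are
#' unreliable. For every pair of successive crossovers on the same meiosis
#' and chromosome whose midpoint-to-midpoint distance is below `minSep`,
#' both events are removed and the spanned region is added to the meiosis's
#' masked-region list; the rule is applied iteratively until no violating
#' pair remains.
#'
#' @param m a [MeiosisSet-class] (crossovers sorted or not; they are sorted
#'   internally).
#' @param minSep minimum separation in bp (default 3 Mb).
#' @return the cleaned [MeiosisSet-class] with masked regions appended.
#' @export
maskCloseDoubleCrossovers <- function(m, minSep = 3e6) {
  co <- crossovers(m)
  masked <- maskedRegions(m)
  if (!nrow(co)) return(m)
  co <- co[order(co$meiosis, co$chrom, co$left, co$right), ]
  keyList <- split(seq_len(nrow(co)), paste(co$meiosis, co$chrom))
  drop <- logical(nrow(co))
  newMask <- list()
  for (idx in keyList) {
    repeat {
      live <- idx[!drop[idx]]
      if (length(live) < 2L) break
      mid <- (co$left[live] + co$right[live]) / 2
      gaps <- diff(mid)
      v <- which(gaps < minSep)
      if (!length(v)) break
      i <- v[1]  # handle the leftmost violating pair, then re-scan
      pair <- live[c(i, i + 1L)]
      drop[pair] <- TRUE
      newMask[[length(newMask) + 1]] <- data.frame(
        meiosis = co$meiosis[pair[1]], chrom = co$chrom[pair[1]],
        start = co$left[pair[1]], end = co$right[pair[2]])
    }
  }
  co2 <- co[!drop, , drop = FALSE]
  if (length(newMask))
    masked <- rbind(masked, do.call(rbind, newMask))
  MeiosisSet(meioses(m), co2, masked)
}

#' Detect, QC and re-detect crossovers
#'
#' Full detection workflow: detect crossovers, mask close double
#' crossovers, re-detect once with the masked genotypes treated as missing,
#' and apply the mask rule a final time so the output satisfies the
#' minimum-separation invariant.
#'
#' @inheritParams detectMeioses
#' @param minSep passed to [maskCloseDoubleCrossovers()].
#' @return a [MeiosisSet-class].
#' @export
detectAndQc <- function(x, ped, fids = selectFids(ped), minSupport = 3L,
                        minSep = 3e6) {
  m1 <- detectMeioses(x, ped, fids, minSupport)
  m2 <- maskCloseDoubleCrossovers(m1, minSep)
  if (!nrow(maskedRegions(m2))) return(m2)
  m3 <- detectMeioses(x, ped, fids, minSupport,
                      maskedRegions = maskedRegions(m2))
  maskCloseDoubleCrossovers(m3, minSep)
}

## ---------------------------------------------------------------------------
## Monte-Carlo window rates
## ---------------------------------------------------------------------------

#' Estimate windowed recombination rates by Monte-Carlo allocation
#'
#' Each detected crossover is only known to lie between its bounding
#' informative markers. Per Monte-Carlo replicate, every crossover is
#' placed uniformly within its bounding interval and counted into fixed
#' windows; counts are averaged over replicates. The window rate in cM/Mb
#' is `100 * meanCount / (nMeioses * windowMb)`; the last (partial) window
#' of each chromosome uses its true length. The total genetic length in
#' Morgans (mean crossovers per meiosis) is recorded on the result.
#'
#' @param m a [MeiosisSet-class] with at least one meiosis.
#' @param genome a [GenomeIndex-class].
#' @param window window size in bp (default 1 Mb).
#' @param nMc Monte-Carlo replicates (default 100).
#' @param seed integer seed; results are deterministic given the seed.
#' @param sex restrict to meioses of this parent sex (`"male"`,
#'   `"female"`), default all.
#' @return a [WindowMap-class] with metadata columns `rate` (cM/Mb) and
#'   `count` (mean crossovers per window).
#' @export
estimateWindowRatesMc <- function(m, genome, window = 1e6, nMc = 100L,
                                  seed = 1L, sex = NULL) {
  mm <- meioses(m)
  co <- crossovers(m)
  if (!is.null(sex)) {
    mm <- mm[mm$sex == sex, , drop = FALSE]
    co <- co[co$sex == sex, , drop = FALSE]
  }
  nMei <- nrow(mm)
  if (nMei == 0L) stop("no meioses to estimate from")
  if (nMc < 1L) stop("nMc must be >= 1")
  tiles <- list()
  for (ci in seq_along(chromNames(genome))) {
    chrom <- chromNames(genome)[ci]
    len <- genome@length[ci]
    starts <- seq(0, len - 1, by = window)
    ends <- pmin(starts + window, len)
    tiles[[chrom]] <- data.frame(chrom = chrom, start = starts, end = ends)
  }
  tiles <- do.call(rbind, tiles)
  counts <- matrix(0, nrow(tiles), 1)
  total <- numeric(nrow(tiles))
  withSeed(seed, {
    for (r in seq_len(nMc)) {
      if (nrow(co)) {
        pos <- runif(nrow(co), co$left, co$right)
        for (chrom in unique(co$chrom)) {
          sel <- co$chrom == chrom
          trow <- which(tiles$chrom == chrom)
          b <- c(tiles$start[trow], tiles$end[trow][length(trow)])
          h <- findInterval(pos[sel], b, rightmost.closed = TRUE)
          h <- h[h >= 1 & h <= length(trow)]
          tb <- tabulate(h, nbins = length(trow))
          total[trow] <- total[trow] + tb
        }
      }
    }
  })
  meanCount <- total / nMc
  mb <- (tiles$end - tiles$start) / 1e6
  rate <- 100 * meanCount / (nMei * mb)
  gr <- grFromBed0(tiles$chrom, tiles$start, tiles$end)
  S4Vectors::mcols(gr)$rate <- rate
  S4Vectors::mcols(gr)$count <- meanCount
  sexLabel <- if (is.null(sex)) "both" else sex
  WindowMap(gr, sex = sexLabel, nMeioses = nMei,
            geneticLength = nrow(co) / nMei)
}

## ---------------------------------------------------------------------------
## ACM comparison
## ---------------------------------------------------------------------------

#' Per-FID average number of crossovers per meiosis (ACM)
#'
#' @param m a [MeiosisSet-class].
#' @return data.frame: `fid`, `sex`, `population`, `nMeioses`,
#'   `nCrossovers`, `acm`.
#' @export
acmTable <- function(m) {
  mm <- meioses(m)
  co <- crossovers(m)
  nMei <- table(mm$fid)
  nCo <- table(factor(co$meiosis, levels = mm$meiosis))
  coPerFid <- tapply(as.integer(nCo), mm$fid, sum)
  fid <- names(nMei)
  data.frame(fid = fid,
             sex = mm$sex[match(fid, mm$fid)],
             population = mm$population[match(fid, mm$fid)],
             nMeioses = as.integer(nMei),
             nCrossovers = as.integer(coPerFid[fid]),
             acm = as.numeric(coPerFid[fid]) / as.integer(nMei),
             row.names = NULL)
}

#' Compare ACM between populations by pairwise F-tests
#'
#' Per-FID ACM values are compared between each pair of populations within
#' each sex by a one-way ANOVA F-test. Pairs where either group has fewer
#' than 2 FIDs are skipped with a warning.
#'
#' @param m a [MeiosisSet-class].
#' @return data.frame: `sex`, `pop1`, `pop2`, `n1`, `n2`, `F`, `df1`,
#'   `df2`, `p` (zero rows when no comparable pair exists).
#' @export
acmCompare <- function(m) {
  acm <- acmTable(m)
  out <- list()
  for (sx in unique(acm$sex)) {
    sub <- acm[acm$sex == sx, ]
    pops <- sort(unique(sub$population))
    if (length(pops) < 2L) next
    for (i in seq_len(length(pops) - 1)) for (j in (i + 1):length(pops)) {
      a <- sub$acm[sub$population == pops[i]]
      b <- sub$acm[sub$population == pops[j]]
      if (length(a) < 2L || length(b) < 2L) {
        warning("skipping ", pops[i], " vs ", pops[j], " (", sx,
                "): group with < 2 FIDs")
        next
      }
      vals <- c(a, b)
      grp <- factor(rep(c("a", "b"), c(length(a), length(b))))
      if (stats::var(vals) == 0) {
        Fst <- 0; p <- 1
        df1 <- 1L; df2 <- length(vals) - 2L
      } else {
        fit <- oneway.test(vals ~ grp, var.equal = TRUE)
        Fst <- unname(fit$statistic); p <- fit$p.value
        df1 <- unname(fit$parameter[1]); df2 <- unname(fit$parameter[2])
      }
      out[[length(out) + 1]] <- data.frame(
        sex = sx, pop1 = pops[i], pop2 = pops[j],
        n1 = length(a), n2 = length(b),
        F = Fst, df1 = df1, df2 = df2, p = p)
    }
  }
  if (!length(out))
    return(data.frame(sex = character(), pop1 = character(),
                      pop2 = character(), n1 = integer(), n2 = integer(),
                      F = numeric(), df1 = numeric(), df2 = numeric(),
                      p = numeric()))
  do.call(rbind, out)
}
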