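## Synthetic-data module: generates every input the pipeline consumes with a
## recorded ground truth, emulating the statistical structure the analysis
## assumes (fine-scale rate landscape with planted hot/coldspots,
## chip-density pedigree genotypes with known crossovers, interval sequences
## with GC bias and planted motifs, variant tables with a diversity
## contrast, and TSS/peak annotations).

#' Simulation configuration
#'
#' Holds every tunable of the synthetic-data generators. Defaults describe a
#' desk-scale single-chromosome study: a 10 Mb chromosome, whole-genome-like
#' SNP spacing of 500 bp for the fine-scale map, chip-like 50 kb marker
#' spacing for the pedigree panel, 20 planted hotspots at 50-fold the
#' background rate and 10 broad coldspots at 0.02-fold, lognormal rate noise
#' (sdlog 0.3), GC fractions and segregating-site densities chosen so that
#' hotspot/coldspot GC and nucleotide diversity contrasts match the
#' magnitudes reported for the pig genome (GC 46.46\% vs 40.53\% around a
#' 42.96\% background; pi 0.00291 vs 0.00198 with 72 haplotypes under a
#' neutral 1/j frequency spectrum), and promoter-like annotation densities
#' (8 genes and 7 peaks per Mb, 63.5\% of peaks near a TSS).
#'
#' @slot seed integer master seed; every generator derives its own child
#'   seed from it via [stageSeed()].
#' @slot chrom chromosome name.
#' @slot chromLength chromosome length, bp.
#' @slot snpSpacing mean inter-SNP spacing (bp, exponential).
#' @slot backgroundRate background per-interval recombination rate.
#' @slot hotspotCount,hotspotWidthRange,hotspotFold planted hotspots: count,
#'   width range (bp) and rate multiplier.
#' @slot coldspotCount,coldspotWidthRange,coldspotFold planted coldspots.
#' @slot rateNoiseSd sdlog of multiplicative lognormal rate noise.
#' @slot nFids,offspringPerFid,markerSpacing,genotypeErrorRate,enforceObligateCrossover
#'   pedigree panel: FID count, offspring per FID, marker grid spacing (bp),
#'   per-genotype error probability, and whether zero-crossover meioses are
#'   resampled.
#' @slot gcBackground,gcHotspot GC fraction outside/inside hotspots.
#' @slot motifPlantRateHot,motifPlantRateCold probability that a
#'   hotspot/coldspot sequence receives one planted motif consensus.
#' @slot nHaplotypes,siteDensityHot,siteDensityCold population variant
#'   panel: haplotype count and segregating-site densities (sites/bp)
#'   inside hotspots/coldspots (the background uses their mean).
#' @slot nGenes,nPeaks,peakTssFraction annotation panel: gene count, peak
#'   count, and fraction of peaks placed within 3 kb of a TSS.
#' @export
setClass("SimConfig",
  representation(seed = "integer", chrom = "character",
    chromLength = "numeric", snpSpacing = "numeric",
    backgroundRate = "numeric", hotspotCount = "integer",
    hotspotWidthRange = "numeric", hotspotFold = "numeric",
    coldspotCount = "integer", coldspotWidthRange = "numeric",
    coldspotFold = "numeric", rateNoiseSd = "numeric",
    nFids = "integer", offspringPerFid = "integer",
    markerSpacing = "numeric", genotypeErrorRate = "numeric",
    enforceObligateCrossover = "logical",
    gcBackground = "numeric", gcHotspot = "numeric",
    motifPlantRateHot = "numeric", motifPlantRateCold = "numeric",
    nHaplotypes = "integer", siteDensityHot = "numeric",
    siteDensityCold = "numeric", nGenes = "integer", nPeaks = "integer",
    peakTssFraction = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- character()
  probs <- c(object@genotypeErrorRate, object@motifPlantRateHot,
             object@motifPlantRateCold, object@peakTssFraction,
             object@gcBackground, object@gcHotspot)
  if (any(probs < 0 | probs > 1))
    msg <- c(msg, "probabilities and fractions must be in [0, 1]")
  if (object@hotspotFold <= 0 || object@coldspotFold <= 0)
    msg <- c(msg, "fold multipliers must be > 0")
  if (max(object@hotspotWidthRange, object@coldspotWidthRange) >=
      object@chromLength)
    msg <- c(msg, "planted interval widths must be < chrom_length")
  if (object@chromLength <= 0 || object@snpSpacing <= 0)
    msg <- c(msg, "chromLength and snpSpacing must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param seed,chrom,chromLength,snpSpacing,backgroundRate,hotspotCount,hotspotWidthRange,hotspotFold,coldspotCount,coldspotWidthRange,coldspotFold,rateNoiseSd,nFids,offspringPerFid,markerSpacing,genotypeErrorRate,enforceObligateCrossover,gcBackground,gcHotspot,motifPlantRateHot,motifPlantRateCold,nHaplotypes,siteDensityHot,siteDensityCold,nGenes,nPeaks,peakTssFraction
#'   see the slot documentation.
#' @return `simConfig()` returns a [SimConfig-class] object.
#' @rdname SimConfig-class
#' @examples
#' cfg <- simConfig(seed = 1, chromLength = 1e6)
#' @export
simConfig <- function(seed = 1L, chrom = "chr1", chromLength = 1e7,
                      snpSpacing = 500, backgroundRate = 0.001,
                      hotspotCount = 20L, hotspotWidthRange = c(2000, 3200),
                      hotspotFold = 50, coldspotCount = 10L,
                      coldspotWidthRange = c(5000, 15000),
                      coldspotFold = 0.02, rateNoiseSd = 0.3,
                      nFids = 30L, offspringPerFid = 10L,
                      markerSpacing = 50000, genotypeErrorRate = 0.002,
                      enforceObligateCrossover = FALSE,
                      gcBackground = 0.4296, gcHotspot = 0.4646,
                      motifPlantRateHot = 0.8, motifPlantRateCold = 0.05,
                      nHaplotypes = 72L, siteDensityHot = 0.0141,
                      siteDensityCold = 0.0096, nGenes = 80L,
                      nPeaks = 72L, peakTssFraction = 0.635) {
  new("SimConfig", seed = as.integer(seed), chrom = chrom,
      chromLength = chromLength, snpSpacing = snpSpacing,
      backgroundRate = backgroundRate, hotspotCount = as.integer(hotspotCount),
      hotspotWidthRange = hotspotWidthRange, hotspotFold = hotspotFold,
      coldspotCount = as.integer(coldspotCount),
      coldspotWidthRange = coldspotWidthRange, coldspotFold = coldspotFold,
      rateNoiseSd = rateNoiseSd, nFids = as.integer(nFids),
      offspringPerFid = as.integer(offspringPerFid),
      markerSpacing = markerSpacing, genotypeErrorRate = genotypeErrorRate,
      enforceObligateCrossover = enforceObligateCrossover,
      gcBackground = gcBackground, gcHotspot = gcHotspot,
      motifPlantRateHot = motifPlantRateHot,
      motifPlantRateCold = motifPlantRateCold,
      nHaplotypes = as.integer(nHaplotypes),
      siteDensityHot = siteDensityHot, siteDensityCold = siteDensityCold,
      nGenes = as.integer(nGenes), nPeaks = as.integer(nPeaks),
      peakTssFraction = peakTssFraction)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig | seed", object@seed, "|", object@chrom,
      format(object@chromLength, big.mark = ","), "bp |",
      object@hotspotCount, "hotspots x", object@hotspotFold, "fold,",
      object@coldspotCount, "coldspots\n")
})

#' Ground truth of a simulated dataset
#'
#' Records everything needed to score the downstream stages: planted
#' hotspot/coldspot intervals, the noiseless per-interval rates, the true
#' crossover position of every simulated meiosis, and every planted motif
#' occurrence.
#'
#' @slot hotspots,coldspots `GRanges` of planted intervals.
#' @slot trueRates numeric noiseless per-interval rates (parallel to the
#'   generated [FineScaleMap-class]).
#' @slot crossoverTruth data.frame: `meiosis`, `chrom`, `pos`, `sex`.
#' @slot motifPlants data.frame: `class`, `interval`, `chrom`, `start`,
#'   `end` (1-based, closed), `strand`.
#' @slot genome the [GenomeIndex-class] the truth lives on.
#' @export
setClass("TruthSet",
  representation(hotspots = "GRanges", coldspots = "GRanges",
                 trueRates = "numeric", crossoverTruth = "data.frame",
                 motifPlants = "data.frame", genome = "GenomeIndex"))

emptyTruth <- function(genome) {
  new("TruthSet", hotspots = GenomicRanges::GRanges(),
      coldspots = GenomicRanges::GRanges(), trueRates = numeric(0),
      crossoverTruth = data.frame(meiosis = character(),
        chrom = character(), pos = numeric(), sex = character()),
      motifPlants = data.frame(class = character(), interval = integer(),
        chrom = character(), start = numeric(), end = numeric(),
        strand = character()),
      genome = genome)
}

#' @param genome a [GenomeIndex-class].
#' @param hotspots,coldspots `GRanges` of planted intervals.
#' @param trueRates,crossoverTruth,motifPlants optional truth components.
#' @return `truthSet()` returns a [TruthSet-class].
#' @rdname TruthSet-class
#' @export
truthSet <- function(genome, hotspots = GenomicRanges::GRanges(),
                     coldspots = GenomicRanges::GRanges(),
                     trueRates = numeric(0), crossoverTruth = NULL,
                     motifPlants = NULL) {
  out <- emptyTruth(genome)
  out@hotspots <- hotspots
  out@coldspots <- coldspots
  out@trueRates <- trueRates
  if (!is.null(crossoverTruth)) out@crossoverTruth <- crossoverTruth
  if (!is.null(motifPlants)) out@motifPlants <- motifPlants
  out
}

#' @param x a `TruthSet`.
#' @rdname TruthSet-class
#' @export
trueHotspots <- function(x) x@hotspots

#' @rdname TruthSet-class
#' @export
trueColdspots <- function(x) x@coldspots

#' @rdname TruthSet-class
#' @export
trueCrossovers <- function(x) x@crossoverTruth

#' @rdname TruthSet-class
#' @export
motifPlants <- function(x) x@motifPlants

setMethod("show", "TruthSet", function(object) {
  cat("TruthSet |", length(object@hotspots), "hotspots,",
      length(object@coldspots), "coldspots,",
      nrow(object@crossoverTruth), "crossovers,",
      nrow(object@motifPlants), "motif plants\n")
})

## ---------------------------------------------------------------------------
## Fine-scale map
## ---------------------------------------------------------------------------

#' Simulate a fine-scale recombination landscape with planted hot/coldspots
#'
#' SNP positions follow exponential spacing along the chromosome. Each
#' inter-SNP interval carries the background rate multiplied by the hotspot
#' fold when its midpoint lies in a planted hotspot, by the coldspot fold in
#' a planted coldspot, and everywhere by multiplicative lognormal noise
#' (`exp(N(0, rateNoiseSd))`; sd 0 means no noise).
#'
#' @param config a [SimConfig-class].
#' @return list with elements `map` ([FineScaleMap-class]) and `truth`
#'   ([TruthSet-class]).
#' @examples
#' sim <- simulateFineMap(simConfig(seed = 7, chromLength = 1e6,
#'                                  hotspotCount = 3L, coldspotCount = 1L))
#' sim$map
#' @export
simulateFineMap <- function(config) {
  validObject(config)
  withSeed(stageSeed(config@seed, "fine_map"), {
    L <- config@chromLength
    ## SNP positions: exponential gaps, 0-based
    nGuess <- ceiling(L / config@snpSpacing * 1.3) + 50
    gaps <- rexp(nGuess, rate = 1 / config@snpSpacing)
    pos <- cumsum(gaps)
    while (pos[length(pos)] < L) {
      pos <- c(pos, pos[length(pos)] +
                 cumsum(rexp(nGuess, 1 / config@snpSpacing)))
    }
    pos <- floor(pos[pos < L])
    pos <- unique(pos)
    if (length(pos) < 2L) stop("chromosome too short for snpSpacing")

    ## plant intervals (hotspots then coldspots, jointly non-overlapping)
    nh <- config@hotspotCount; nc <- config@coldspotCount
    widths <- c(
      if (nh) floor(runif(nh, config@hotspotWidthRange[1],
                          config@hotspotWidthRange[2])) else numeric(0),
      if (nc) floor(runif(nc, config@coldspotWidthRange[1],
                          config@coldspotWidthRange[2])) else numeric(0))
    planted <- placeNonOverlapping(widths, L)
    hot <- planted[seq_len(nh), , drop = FALSE]
    cold <- planted[nh + seq_len(nc), , drop = FALSE]
    hotGr <- grFromBed0(config@chrom, hot$start, hot$end)
    coldGr <- grFromBed0(config@chrom, cold$start, cold$end)

    ## per-interval rates
    mid <- (pos[-length(pos)] + pos[-1]) / 2
    fold <- rep(1, length(mid))
    inHot <- IRanges::overlapsAny(
      GenomicRanges::GRanges(config@chrom, IRanges::IRanges(mid + 1, mid + 1)),
      hotGr)
    inCold <- IRanges::overlapsAny(
      GenomicRanges::GRanges(config@chrom, IRanges::IRanges(mid + 1, mid + 1)),
      coldGr)
    fold[inHot] <- config@hotspotFold
    fold[inCold] <- config@coldspotFold
    trueRates <- config@backgroundRate * fold
    noise <- if (config@rateNoiseSd > 0)
      rlnorm(length(mid), 0, config@rateNoiseSd) else rep(1, length(mid))
    rates <- trueRates * noise

    map <- FineScaleMap(config@chrom, pos, rates, units = "rho/bp",
                        source = "simulateFineMap")
    truth <- emptyTruth(GenomeIndex(config@chrom, L))
    truth@hotspots <- hotGr
    truth@coldspots <- coldGr
    truth@trueRates <- trueRates
    list(map = map, truth = truth)
  })
}

## ---------------------------------------------------------------------------
## Pedigree meioses
## ---------------------------------------------------------------------------

## cumulative genetic position (Morgans) evaluated by linear interpolation;
## returns list(fun = genetic->physical inverse, total = Morgans)
geneticCdf <- function(geneticMap) {
  if (is(geneticMap, "WindowMap")) {
    gr <- windowRanges(geneticMap)
    bp <- c(GenomicRanges::start(gr)[1] - 1, GenomicRanges::end(gr))
    r <- windowRates(geneticMap)            # cM/Mb
    r[is.na(r)] <- 0
    seg <- r * (diff(bp) / 1e6) / 100       # Morgans per window
  } else if (is(geneticMap, "FineScaleMap")) {
    if (!identical(geneticMap@units, "cM/Mb"))
      stop("genetic map must be in cM/Mb units")
    bp <- snpPositions(geneticMap)
    seg <- intervalRates(geneticMap) * (diff(bp) / 1e6) / 100
  } else stop("geneticMap must be a WindowMap or FineScaleMap")
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) stop("total genetic length must be > 0 Morgans")
  inv <- function(u) {  # u in Morgans -> physical bp
    i <- findInterval(u, cum, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), length(seg))
    frac <- ifelse(seg[i] > 0, (u - cum[i]) / seg[i], 0.5)
    bp[i] + frac * (bp[i + 1] - bp[i])
  }
  list(inverse = inv, total = total, bpRange = range(bp))
}

#' Simulate pedigree genotypes with known crossovers
#'
#' Builds `nFids` focal individuals (FIDs), each with two (ungenotyped)
#' founder parents and `offspringPerFid` offspring; every offspring has its
#' own unrelated mate, as in multi-mate livestock pedigrees. Per meiosis the
#' crossover count is Poisson with mean equal to the genetic length of
#' `geneticMap` (optionally resampled to be >= 1 when
#' `enforceObligateCrossover`), crossover positions are placed by the
#' inverse CDF of the cumulative genetic map, and the FID gamete is read off
#' a random starting haplotype. Offspring genotypes at a regular marker grid
#' receive independent errors at `genotypeErrorRate` (the erroneous call is
#' uniform over the other two dosages). Mate gametes are transmitted without
#' recombination, so the recorded truth (FID crossovers) is complete.
#'
#' @param config a [SimConfig-class].
#' @param geneticMap a [WindowMap-class] or a [FineScaleMap-class] with
#'   `cM/Mb` units, defining the crossover intensity landscape.
#' @return list with elements `variants` ([VariantTable-class] over all
#'   genotyped individuals), `pedigree` (data.frame: `id`, `sire`, `dam`,
#'   `sex`, `population`) and `truth` ([TruthSet-class] carrying the true
#'   crossover positions; meiosis ids are `"<fid>_<offspring>"`).
#' @export
simulatePedigreeMeioses <- function(config, geneticMap) {
  validObject(config)
  cdf <- geneticCdf(geneticMap)
  withSeed(stageSeed(config@seed, "pedigree"), {
    L <- config@chromLength
    markers <- seq(0, L - 1, by = config@markerSpacing)  # 0-based
    nm <- length(markers)
    freq <- runif(nm, 0.1, 0.9)  # chip-like common variants

    nF <- config@nFids; nOff <- config@offspringPerFid
    fids <- sprintf("FID%03d", seq_len(nF))
    fidSex <- rep(c("male", "female"), length.out = nF)
    ped <- data.frame(id = character(), sire = character(),
                      dam = character(), sex = character(),
                      population = character())
    ## founder parents of each FID (ungenotyped)
    for (i in seq_len(nF)) {
      ped <- rbind(ped, data.frame(
        id = c(paste0(fids[i], "_S"), paste0(fids[i], "_D"), fids[i]),
        sire = c(NA, NA, paste0(fids[i], "_S")),
        dam = c(NA, NA, paste0(fids[i], "_D")),
        sex = c("male", "female", fidSex[i]),
        population = "simpop"))
    }

    drawHap <- function() as.integer(rbinom(nm, 1, freq))
    geno <- list()
    truthCo <- list()
    for (i in seq_len(nF)) {
      h1 <- drawHap(); h2 <- drawHap()
      geno[[fids[i]]] <- h1 + h2
      for (k in seq_len(nOff)) {
        offId <- sprintf("%s_O%02d", fids[i], k)
        mateId <- sprintf("%s_M%02d", fids[i], k)
        mh1 <- drawHap(); mh2 <- drawHap()
        geno[[mateId]] <- mh1 + mh2
        ## FID meiosis
        nco <- rpois(1, cdf$total)
        if (config@enforceObligateCrossover)
          while (nco == 0) nco <- rpois(1, cdf$total)
        copos <- sort(cdf$inverse(runif(nco, 0, cdf$total)))
        startHap <- sample(1:2, 1)
        hapIdx <- (startHap - 1 + findInterval(markers, copos)) %% 2 + 1
        gamete <- ifelse(hapIdx == 1L, h1, h2)
        mate <- if (runif(1) < 0.5) mh1 else mh2
        g <- gamete + mate
        if (config@genotypeErrorRate > 0) {
          err <- runif(nm) < config@genotypeErrorRate
          if (any(err)) {
            g[err] <- vapply(g[err],
              function(v) sample(setdiff(0:2, v), 1), integer(1))
          }
        }
        geno[[offId]] <- g
        mid <- paste0(fids[i], "_", offId)
        if (nco > 0)
          truthCo[[mid]] <- data.frame(meiosis = mid, chrom = config@chrom,
                                       pos = copos, sex = fidSex[i])
        sx <- fidSex[i]
        ped <- rbind(ped, data.frame(
          id = c(mateId, offId),
          sire = c(NA, if (sx == "male") fids[i] else mateId),
          dam = c(NA, if (sx == "male") mateId else fids[i]),
          sex = c(if (sx == "male") "female" else "male", "unknown"),
          population = "simpop"))
      }
    }
    gm <- do.call(cbind, geno)
    sites <- data.frame(chrom = config@chrom, pos = markers + 1,
                        ref = "A", alt = "G", qual = 100,
                        depth = NA_real_)
    vt <- VariantTable(sites, gm)
    truth <- emptyTruth(GenomeIndex(config@chrom, L))
    truth@crossoverTruth <- if (length(truthCo))
      do.call(rbind, c(truthCo, list(make.row.names = FALSE))) else
      truth@crossoverTruth
    ## meioses with zero crossovers still exist; record the full meiosis list
    allMei <- unlist(lapply(seq_len(nF), function(i)
      sprintf("%s_%s_O%02d", fids[i], fids[i], seq_len(nOff))))
    attr(truth, "allMeioses") <- allMei
    list(variants = vt, pedigree = ped, truth = truth)
  })
}

## ---------------------------------------------------------------------------
## Sequences
## ---------------------------------------------------------------------------

randomDna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Simulate genome sequence with GC bias and planted motif occurrences
#'
#' Generates i.i.d. bases along the whole chromosome with GC fraction
#' `gcHotspot` inside planted hotspots and `gcBackground` elsewhere. The PWM
#' consensus is planted once per hotspot with probability
#' `motifPlantRateHot` (random offset, random strand) and per coldspot with
#' probability `motifPlantRateCold`; plants are recorded in the truth.
#'
#' @param config a [SimConfig-class].
#' @param truth a [TruthSet-class] carrying planted hotspots/coldspots
#'   (from [simulateFineMap()]).
#' @param pwm a [PWM-class]; its consensus is what gets planted.
#' @return list with `sequences` (a [Biostrings::DNAStringSet] holding the
#'   chromosome) and `truth` (input truth with `motifPlants` filled in,
#'   1-based closed coordinates).
#' @export
simulateSequences <- function(config, truth, pwm) {
  validObject(config)
  if (config@gcBackground < 0 || config@gcBackground > 1 ||
      config@gcHotspot < 0 || config@gcHotspot > 1)
    stop("gc fractions must be in [0, 1]")
  hot <- trueHotspots(truth); cold <- trueColdspots(truth)
  if (length(hot) && motifLength(pwm) > min(GenomicRanges::width(hot)))
    stop("PWM longer than the shortest planted interval")
  withSeed(stageSeed(config@seed, "sequences"), {
    L <- config@chromLength
    seqchar <- strsplit(randomDna(L, config@gcBackground), "")[[1]]
    for (i in seq_along(hot)) {
      s <- GenomicRanges::start(hot)[i]; e <- GenomicRanges::end(hot)[i]
      seqchar[s:e] <- strsplit(randomDna(e - s + 1, config@gcHotspot),
                               "")[[1]]
    }
    cons <- pwmConsensus(pwm)
    m <- nchar(cons)
    plantInto <- function(gr, rate, cls) {
      out <- list()
      for (i in seq_along(gr)) {
        if (runif(1) >= rate) next
        s <- GenomicRanges::start(gr)[i]; e <- GenomicRanges::end(gr)[i]
        off <- s + floor(runif(1, 0, e - s + 1 - m + 1))
        strand <- if (runif(1) < 0.5) "+" else "-"
        ins <- if (strand == "+") cons else
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
        seqchar[off:(off + m - 1)] <<- strsplit(ins, "")[[1]]
        out[[length(out) + 1]] <- data.frame(class = cls, interval = i,
          chrom = config@chrom, start = off, end = off + m - 1,
          strand = strand)
      }
      out
    }
    plants <- c(plantInto(hot, config@motifPlantRateHot, "hotspot"),
                plantInto(cold, config@motifPlantRateCold, "coldspot"))
    truth@motifPlants <- if (length(plants))
      do.call(rbind, plants) else truth@motifPlants
    dss <- Biostrings::DNAStringSet(paste(seqchar, collapse = ""))
    names(dss) <- config@chrom
    list(sequences = dss, truth = truth)
  })
}

## ---------------------------------------------------------------------------
## Population variants (for nucleotide diversity)
## ---------------------------------------------------------------------------

#' Simulate a population variant table with a diversity contrast
#'
#' Segregating sites are placed as a Poisson process with density
#' `siteDensityHot` inside planted hotspots, `siteDensityCold` inside
#' coldspots and the mean of the two elsewhere. The derived-allele count of
#' each site is drawn from the neutral frequency spectrum (probability
#' proportional to 1/j for j = 1..n-1) over `nHaplotypes` haplotypes, and
#' carriers are assigned at random.
#'
#' @param config a [SimConfig-class].
#' @param truth a [TruthSet-class] with planted hotspots/coldspots.
#' @return a [VariantTable-class] with an explicit haplotype matrix.
#' @export
simulateVariants <- function(config, truth) {
  validObject(config)
  withSeed(stageSeed(config@seed, "variants"), {
    L <- config@chromLength
    n <- config@nHaplotypes
    bgDensity <- mean(c(config@siteDensityHot, config@siteDensityCold))
    hot <- trueHotspots(truth); cold <- trueColdspots(truth)
    segments <- data.frame(start = 1, end = L, density = bgDensity)
    addSeg <- function(gr, d) {
      if (!length(gr)) return(NULL)
      data.frame(start = GenomicRanges::start(gr),
                 end = GenomicRanges::end(gr), density = d)
    }
    special <- rbind(addSeg(hot, config@siteDensityHot),
                     addSeg(cold, config@siteDensityCold))
    pos <- floor(runif(rpois(1, bgDensity * L), 1, L + 1))
    if (!is.null(special)) {
      inSpecial <- rep(FALSE, length(pos))
      for (k in seq_len(nrow(special)))
        inSpecial <- inSpecial | (pos >= special$start[k] &
                                  pos <= special$end[k])
      pos <- pos[!inSpecial]
      for (k in seq_len(nrow(special))) {
        w <- special$end[k] - special$start[k] + 1
        nk <- rpois(1, special$density[k] * w)
        if (nk) pos <- c(pos, floor(runif(nk, special$start[k],
                                          special$end[k] + 1)))
      }
    }
    pos <- sort(unique(pos))
    ns <- length(pos)
    ## neutral 1/j spectrum
    j <- if (n == 2L) rep(1L, ns) else
      sample(seq_len(n - 1), ns, replace = TRUE,
             prob = 1 / seq_len(n - 1))
    hap <- matrix(0L, nrow = ns, ncol = n)
    for (i in seq_len(ns)) hap[i, sample.int(n, j[i])] <- 1L
    sites <- data.frame(chrom = config@chrom, pos = pos, ref = "A",
                        alt = "G", qual = 100, depth = NA_real_)
    VariantTable(sites, haplotypes = hap)
  })
}

## ---------------------------------------------------------------------------
## Annotations
## ---------------------------------------------------------------------------

#' Simulate TSS and peak annotations
#'
#' Places `nGenes` transcription start sites uniformly with random strand;
#' each of `nPeaks` peaks is centred within +/- 3 kb of a random TSS with
#' probability `peakTssFraction` and placed uniformly otherwise.
#'
#' @param config a [SimConfig-class].
#' @param peakWidth peak width in bp (default 1648, a typical promoter-mark
#'   peak width).
#' @return list with `tss` (data.frame: `gene_id`, `chrom`, `tss` 0-based
#'   bp, `strand`) and `peaks` (`GRanges`).
#' @export
simulateAnnotations <- function(config, peakWidth = 1648) {
  validObject(config)
  if (config@nGenes == 0L && config@peakTssFraction > 0)
    stop("cannot place peaks near TSSs when nGenes is 0")
  withSeed(stageSeed(config@seed, "annotations"), {
    L <- config@chromLength
    tss <- data.frame(
      gene_id = sprintf("gene%04d", seq_len(config@nGenes)),
      chrom = config@chrom,
      tss = floor(runif(config@nGenes, 0, L)),
      strand = sample(c("+", "-"), config@nGenes, replace = TRUE))
    centers <- numeric(config@nPeaks)
    for (i in seq_len(config@nPeaks)) {
      if (config@nGenes > 0 && runif(1) < config@peakTssFraction) {
        t0 <- tss$tss[sample.int(config@nGenes, 1)]
        centers[i] <- t0 + floor(runif(1, -3000, 3001))
      } else {
        centers[i] <- floor(runif(1, 0, L))
      }
    }
    start0 <- pmax(0, pmin(centers - floor(peakWidth / 2), L - peakWidth))
    peaks <- grFromBed0(config@chrom, start0, start0 + peakWidth)
    S4Vectors::mcols(peaks)$name <- sprintf("peak%05d",
                                            seq_len(config@nPeaks))
    list(tss = tss, peaks = peaks)
  })
}
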