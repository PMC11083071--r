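#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom stats aggregate aov cor.test fisher.test ks.test median
#'   oneway.test p.adjust rbinom rexp rlnorm rpois runif sd setNames t.test
#'   wilcox.test rnorm
#' @importFrom utils read.table write.table head tail packageVersion
NULL

## ---------------------------------------------------------------------------
## GenomeIndex
## ---------------------------------------------------------------------------

#' Genome index: ordered chromosome names and lengths
#'
#' A minimal container describing the reference assembly the pipeline works
#' against (chromosome order, names and lengths in bp). Convertible to a
#' [GenomeInfoDb::Seqinfo] for interoperability with `GRanges` operations.
#'
#' @slot chrom character vector of unique chromosome names, in order.
#' @slot length numeric vector of chromosome lengths (bp), all `> 0`.
#' @export
setClass("GenomeIndex",
  representation(chrom = "character", length = "numeric"))

setValidity("GenomeIndex", function(object) {
  msg <- character()
  if (length(object@chrom) != length(object@length))
    msg <- c(msg, "chrom and length must have equal length")
  if (anyDuplicated(object@chrom))
    msg <- c(msg, "chromosome names must be unique")
  if (any(!is.finite(object@length)) || any(object@length <= 0))
    msg <- c(msg, "chromosome lengths must be finite and > 0")
  if (length(msg)) msg else TRUE
})

#' @param chrom,length chromosome names and lengths (bp).
#' @return `GenomeIndex()` returns a [GenomeIndex-class] object.
#' @rdname GenomeIndex-class
#' @examples
#' gi <- GenomeIndex("chr1", 1e7)
#' chromLengths(gi)
#' @export
GenomeIndex <- function(chrom, length) {
  new("GenomeIndex", chrom = as.character(chrom), length = as.numeric(length))
}

#' @param x a `GenomeIndex`.
#' @rdname GenomeIndex-class
#' @export
chromNames <- function(x) x@chrom

#' @rdname GenomeIndex-class
#' @export
chromLengths <- function(x) setNames(x@length, x@chrom)

#' @rdname GenomeIndex-class
#' @export
genomeLength <- function(x) sum(x@length)

#' @rdname GenomeIndex-class
#' @export
asSeqinfo <- function(x) {
  GenomeInfoDb::Seqinfo(seqnames = x@chrom, seqlengths = as.integer(x@length))
}

setMethod("show", "GenomeIndex", function(object) {
  cat("GenomeIndex with", length(object@chrom), "chromosome(s),",
      format(sum(object@length), big.mark = ","), "bp total\n")
})

## ---------------------------------------------------------------------------
## FineScaleMap
## ---------------------------------------------------------------------------

#' Fine-scale recombination map over inter-SNP intervals
#'
#' Stores, for one chromosome, the ordered SNP positions (0-based bp) and one
#' non-negative recombination rate per adjacent SNP pair. This is the
#' container for per-SNP-interval historical maps (population-scaled rate
#' rho per bp) as well as any map defined on irregular intervals.
#'
#' @slot chrom chromosome name (length-1 character).
#' @slot positions strictly increasing numeric SNP coordinates, 0-based bp.
#' @slot rates numeric vector of length `length(positions) - 1`, all `>= 0`.
#' @slot units free-text unit tag, e.g. `"rho/bp"` or `"cM/Mb"`.
#' @slot source free-text provenance tag.
#' @export
setClass("FineScaleMap",
  representation(chrom = "character", positions = "numeric",
                 rates = "numeric", units = "character",
                 source = "character"))

setValidity("FineScaleMap", function(object) {
  msg <- character()
  if (length(object@chrom) != 1L) msg <- c(msg, "chrom must be length 1")
  if (length(object@positions) < 2L)
    msg <- c(msg, "need at least 2 SNP positions")
  if (any(diff(object@positions) <= 0))
    msg <- c(msg, "positions must be strictly increasing")
  if (length(object@rates) != length(object@positions) - 1L)
    msg <- c(msg, "length(rates) must equal length(positions) - 1")
  if (any(!is.finite(object@rates)) || any(object@rates < 0))
    msg <- c(msg, "rates must be finite and >= 0")
  if (length(msg)) msg else TRUE
})

#' @param chrom chromosome name.
#' @param positions strictly increasing SNP coordinates (0-based bp).
#' @param rates per-interval rates, one per adjacent SNP pair.
#' @param units,source unit and provenance tags.
#' @return `FineScaleMap()` returns a [FineScaleMap-class] object.
#' @rdname FineScaleMap-class
#' @examples
#' fsm <- FineScaleMap("chr1", c(0, 100, 300), c(0.1, 0.2))
#' intervalRates(fsm)
#' @export
FineScaleMap <- function(chrom, positions, rates, units = "rho/bp",
                         source = "") {
  new("FineScaleMap", chrom = as.character(chrom),
      positions = as.numeric(positions), rates = as.numeric(rates),
      units = units, source = source)
}

#' @param x a `FineScaleMap`.
#' @rdname FineScaleMap-class
#' @export
snpPositions <- function(x) x@positions

#' @rdname FineScaleMap-class
#' @export
intervalRates <- function(x) x@rates

#' @rdname FineScaleMap-class
#' @export
intervalLengths <- function(x) diff(x@positions)

#' Inter-SNP intervals of a fine-scale map as GRanges
#'
#' Intervals are reported 1-based closed (Bioconductor convention); the i-th
#' range spans from just after SNP i to SNP i+1.
#'
#' @param x a [FineScaleMap-class].
#' @return a [GenomicRanges::GRanges] with an `rate` metadata column.
#' @export
intervalRanges <- function(x) {
  n <- length(x@positions)
  gr <- GenomicRanges::GRanges(x@chrom,
    IRanges::IRanges(start = x@positions[-n] + 1L, end = x@positions[-1L]))
  S4Vectors::mcols(gr)$rate <- x@rates
  gr
}

setMethod("show", "FineScaleMap", function(object) {
  cat("FineScaleMap on", object@chrom, "|",
      length(object@positions), "SNPs,",
      length(object@rates), "intervals [", object@units, "]\n")
  cat("  span:", object@positions[1], "-",
      object@positions[length(object@positions)], "bp; mean rate",
      signif(chromosomeMeanRate(object), 4), "(length-weighted)\n")
})

setMethod("length", "FineScaleMap", function(x) length(x@rates))

## ---------------------------------------------------------------------------
## WindowMap
## ---------------------------------------------------------------------------

#' Windowed recombination map
#'
#' Fixed-width (default 1 Mb) window recombination rates, e.g. the meiotic
#' map estimated from pedigree crossovers (cM/Mb) or a fine-scale map
#' aggregated to windows. Windows with no underlying data carry `NA` rates.
#'
#' @slot windows a `GRanges` tiling (part of) the genome, with numeric
#'   metadata column `rate` and optionally `count`.
#' @slot sex sex label (`"male"`, `"female"` or `"both"`).
#' @slot nMeioses number of meioses behind the estimate (0 when not
#'   applicable, e.g. LD-based maps).
#' @slot geneticLength total genetic length in Morgans (`NA` when not
#'   applicable).
#' @export
setClass("WindowMap",
  representation(windows = "GRanges", sex = "character",
                 nMeioses = "integer", geneticLength = "numeric"))

setValidity("WindowMap", function(object) {
  msg <- character()
  r <- S4Vectors::mcols(object@windows)$rate
  if (is.null(r)) msg <- c(msg, "windows must carry a 'rate' column")
  else if (any(r < 0, na.rm = TRUE)) msg <- c(msg, "rates must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param windows GRanges with a `rate` metadata column.
#' @param sex,nMeioses,geneticLength see slots.
#' @return `WindowMap()` returns a [WindowMap-class] object.
#' @rdname WindowMap-class
#' @export
WindowMap <- function(windows, sex = "both", nMeioses = 0L,
                      geneticLength = NA_real_) {
  new("WindowMap", windows = windows, sex = sex,
      nMeioses = as.integer(nMeioses), geneticLength = geneticLength)
}

#' @param x a `WindowMap`.
#' @rdname WindowMap-class
#' @export
windowRanges <- function(x) x@windows

#' @rdname WindowMap-class
#' @export
windowRates <- function(x) S4Vectors::mcols(x@windows)$rate

#' @rdname WindowMap-class
#' @export
geneticLength <- function(x) x@geneticLength

setMethod("show", "WindowMap", function(object) {
  r <- windowRates(object)
  cat("WindowMap (", object@sex, ") | ", length(object@windows),
      " windows, ", sum(is.na(r)), " missing\n", sep = "")
  if (!is.na(object@geneticLength))
    cat("  genetic length:", round(object@geneticLength, 3), "Morgans from",
        object@nMeioses, "meioses\n")
})

setMethod("length", "WindowMap", function(x) length(x@windows))

## ---------------------------------------------------------------------------
## VariantTable
## ---------------------------------------------------------------------------

#' SNP variant table with genotypes and optional haplotypes
#'
#' Site-level records (1-based positions, per-chromosome strictly
#' increasing) plus a sites x samples diploid genotype matrix in alt-allele
#' dosage coding (0/1/2, `NA` missing). Simulated population data may carry
#' an explicit sites x haplotypes 0/1 matrix, which diversity calculations
#' use in preference to genotypes.
#'
#' @slot sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `qual`, `depth` (site mean depth).
#' @slot geno integer matrix, sites x samples, values in \{0,1,2,NA\}.
#' @slot haplotypes integer matrix, sites x haplotypes, values in \{0,1\};
#'   may have zero columns.
#' @slot meta list of provenance metadata (e.g. the reference mean depth
#'   used by [filterVariants()]).
#' @export
setClass("VariantTable",
  representation(sites = "data.frame", geno = "matrix",
                 haplotypes = "matrix", meta = "list"))

setValidity("VariantTable", function(object) {
  msg <- character()
  need <- c("chrom", "pos", "ref", "alt", "qual", "depth")
  if (!all(need %in% names(object@sites)))
    msg <- c(msg, paste("sites must have columns:",
                        paste(need, collapse = ", ")))
  else {
    bychrom <- split(object@sites$pos, object@sites$chrom)
    if (any(vapply(bychrom, function(p) any(diff(p) <= 0), logical(1))))
      msg <- c(msg, "positions must be strictly increasing within chromosome")
  }
  if (nrow(object@geno) && nrow(object@geno) != nrow(object@sites))
    msg <- c(msg, "geno rows must match sites")
  g <- object@geno
  if (length(g) && !all(g[!is.na(g)] %in% 0:2))
    msg <- c(msg, "genotypes must be in {0,1,2,NA}")
  if (ncol(object@haplotypes) &&
      nrow(object@haplotypes) != nrow(object@sites))
    msg <- c(msg, "haplotype rows must match sites")
  h <- object@haplotypes
  if (length(h) && !all(h[!is.na(h)] %in% 0:1))
    msg <- c(msg, "haplotype alleles must be 0/1")
  if (length(msg)) msg else TRUE
})

#' @param sites,geno,haplotypes,meta see slots.
#' @return `VariantTable()` returns a [VariantTable-class] object.
#' @rdname VariantTable-class
#' @export
VariantTable <- function(sites, geno = NULL, haplotypes = NULL,
                         meta = list()) {
  if (is.null(geno))
    geno <- matrix(integer(0), nrow = nrow(sites), ncol = 0)
  if (is.null(haplotypes))
    haplotypes <- matrix(integer(0), nrow = nrow(sites), ncol = 0)
  rownames(sites) <- NULL
  new("VariantTable", sites = sites, geno = geno,
      haplotypes = haplotypes, meta = meta)
}

#' @param x a `VariantTable`.
#' @rdname VariantTable-class
#' @export
variantSites <- function(x) x@sites

#' @rdname VariantTable-class
#' @export
genotypes <- function(x) x@geno

#' @rdname VariantTable-class
#' @export
haplotypeMatrix <- function(x) x@haplotypes

#' @rdname VariantTable-class
#' @export
nSites <- function(x) nrow(x@sites)

setMethod("show", "VariantTable", function(object) {
  cat("VariantTable |", nrow(object@sites), "sites x",
      ncol(object@geno), "samples",
      if (ncol(object@haplotypes)) paste0("(+", ncol(object@haplotypes),
                                          " haplotypes)") else "", "\n")
})

## subset a VariantTable by site index, keeping metadata
subsetSites <- function(x, i) {
  VariantTable(x@sites[i, , drop = FALSE],
               x@geno[i, , drop = FALSE],
               x@haplotypes[i, , drop = FALSE],
               x@meta)
}

## ---------------------------------------------------------------------------
## MeiosisSet
## ---------------------------------------------------------------------------

#' Set of observed meioses with detected crossovers
#'
#' One meiosis is one focal-individual (FID) to offspring transmission. The
#' crossover table records each event bounded by its flanking informative
#' markers; masked regions accumulate during close-double-crossover QC.
#'
#' @slot meioses data.frame: `meiosis`, `fid`, `offspring`, `sex`,
#'   `population`.
#' @slot crossovers data.frame: `meiosis`, `chrom`, `left`, `right`, `sex`
#'   (left/right are the bounding informative marker positions, bp).
#' @slot masked data.frame: `meiosis`, `chrom`, `start`, `end`.
#' @export
setClass("MeiosisSet",
  representation(meioses = "data.frame", crossovers = "data.frame",
                 masked = "data.frame"))

setValidity("MeiosisSet", function(object) {
  msg <- character()
  co <- object@crossovers
  if (nrow(co)) {
    if (any(co$left >= co$right))
      msg <- c(msg, "crossover left_pos must be < right_pos")
    if (!all(co$meiosis %in% object@meioses$meiosis))
      msg <- c(msg, "crossover meiosis ids must exist in meioses")
  }
  if (length(msg)) msg else TRUE
})

#' @param meioses,crossovers,masked see slots.
#' @return `MeiosisSet()` returns a [MeiosisSet-class] object.
#' @rdname MeiosisSet-class
#' @export
MeiosisSet <- function(meioses, crossovers = NULL, masked = NULL) {
  if (is.null(crossovers))
    crossovers <- data.frame(meiosis = character(), chrom = character(),
                             left = numeric(), right = numeric(),
                             sex = character())
  if (is.null(masked))
    masked <- data.frame(meiosis = character(), chrom = character(),
                         start = numeric(), end = numeric())
  rownames(meioses) <- rownames(crossovers) <- rownames(masked) <- NULL
  new("MeiosisSet", meioses = meioses, crossovers = crossovers,
      masked = masked)
}

#' @param x a `MeiosisSet`.
#' @rdname MeiosisSet-class
#' @export
crossovers <- function(x) x@crossovers

#' @rdname MeiosisSet-class
#' @export
meioses <- function(x) x@meioses

#' @rdname MeiosisSet-class
#' @export
maskedRegions <- function(x) x@masked

#' @rdname MeiosisSet-class
#' @export
nMeioses <- function(x) nrow(x@meioses)

setMethod("show", "MeiosisSet", function(object) {
  cat("MeiosisSet |", nrow(object@meioses), "meioses,",
      nrow(object@crossovers), "crossovers,",
      nrow(object@masked), "masked regions\n")
  if (nrow(object@meioses))
    cat("  ACM:", round(nrow(object@crossovers) / nrow(object@meioses), 3),
        "\n")
})

## ---------------------------------------------------------------------------
## PWM
## ---------------------------------------------------------------------------

#' Position weight matrix
#'
#' An L x 4 base-probability matrix over (A, C, G, T) with background
#' frequencies and a pseudocount used when forming the log-odds view.
#'
#' @slot prob numeric L x 4 matrix, rows summing to 1, columns named
#'   A, C, G, T.
#' @slot background numeric length-4 background frequencies (sum 1).
#' @slot pseudocount numeric, blended with the background in the log-odds.
#' @slot name motif name.
#' @export
setClass("PWM",
  representation(prob = "matrix", background = "numeric",
                 pseudocount = "numeric", name = "character"))

setValidity("PWM", function(object) {
  msg <- character()
  p <- object@prob
  if (ncol(p) != 4L || !identical(colnames(p), c("A", "C", "G", "T")))
    msg <- c(msg, "prob must have 4 columns named A, C, G, T")
  if (nrow(p) < 4L) msg <- c(msg, "motif length must be >= 4")
  if (any(p < 0)) msg <- c(msg, "probabilities must be >= 0")
  if (any(abs(rowSums(p) - 1) > 1e-9))
    msg <- c(msg, "each row of prob must sum to 1")
  if (length(object@background) != 4L ||
      abs(sum(object@background) - 1) > 1e-9)
    msg <- c(msg, "background must be 4 frequencies summing to 1")
  if (length(msg)) msg else TRUE
})

#' @param prob L x 4 probability matrix (columns A, C, G, T).
#' @param background background base frequencies.
#' @param pseudocount pseudocount blended with background.
#' @param name motif name.
#' @return `PWM()` returns a [PWM-class] object.
#' @rdname PWM-class
#' @examples
#' m <- matrix(0.25, 5, 4, dimnames = list(NULL, c("A","C","G","T")))
#' PWM(m, name = "uniform")
#' @export
PWM <- function(prob, background = rep(0.25, 4), pseudocount = 0.01,
                name = "motif") {
  prob <- as.matrix(prob)
  colnames(prob) <- c("A", "C", "G", "T")
  new("PWM", prob = prob, background = background,
      pseudocount = pseudocount, name = name)
}

#' @param x a `PWM`.
#' @rdname PWM-class
#' @export
motifLength <- function(x) nrow(x@prob)

#' Log-odds view of a PWM
#'
#' `log2((p + pseudocount * bg) / (1 + pseudocount) / bg)` per cell, so a
#' uniform PWM on a uniform background scores exactly 0 everywhere.
#'
#' @param x a [PWM-class].
#' @return L x 4 numeric matrix of log2 odds.
#' @export
logOdds <- function(x) {
  bg <- matrix(x@background, nrow = nrow(x@prob), ncol = 4, byrow = TRUE)
  lo <- log2(((x@prob + x@pseudocount * bg) / (1 + x@pseudocount)) / bg)
  colnames(lo) <- c("A", "C", "G", "T")
  lo
}

#' Consensus sequence of a PWM
#'
#' @param x a [PWM-class].
#' @return character consensus (highest-probability base per position; ties
#'   broken towards the alphabetically first base).
#' @export
pwmConsensus <- function(x) {
  paste(c("A", "C", "G", "T")[apply(x@prob, 1, which.max)], collapse = "")
}

setMethod("show", "PWM", function(object) {
  cat("PWM '", object@name, "' | length ", nrow(object@prob),
      ", consensus ", pwmConsensus(object), "\n", sep = "")
})

setMethod("length", "PWM", function(x) nrow(x@prob))
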