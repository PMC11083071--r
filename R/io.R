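## io_formats module: readers/writers for every external format the
## pipeline touches, plus the variant-filter stage. Coordinate conventions:
## all in-memory GRanges are 1-based closed (Bioconductor); BED emission is
## 0-based half-open; VCF positions are 1-based; FineScaleMap SNP positions
## are 0-based bp.

## ---------------------------------------------------------------------------
## Variant filter
## ---------------------------------------------------------------------------

#' Filter a variant table by quality, allele count, frequency and depth
#'
#' Applies the standard WGS site filters: site quality `>= minQual`,
#' biallelic sites only, minor-allele frequency `>= minMaf`, and site mean
#' depth within `depthBounds` times the population mean depth (default
#' one-third to twice the mean). All retention thresholds are inclusive
#' (`>=`). Note the depth reference mean is computed from the incoming
#' table once and stored in the result's metadata (`meta$refMeanDepth`), so
#' the filter is idempotent: re-filtering a filtered table reuses the
#' recorded reference and changes nothing.
#'
#' @param x a [VariantTable-class]; must be non-empty.
#' @param minQual minimum site quality (default 30).
#' @param minMaf minimum minor-allele frequency for retention (default
#'   0.05). Sites with MAF exactly at the threshold are retained.
#' @param biallelicOnly drop sites with more than one alt allele.
#' @param depthBounds length-2 multipliers of the mean depth (default
#'   `c(1/3, 2)`).
#' @return the filtered [VariantTable-class]; attribute `"removed"` carries
#'   the per-rule removal counts. All sites removed gives an empty table
#'   with a warning.
#' @examples
#' sites <- data.frame(chrom = "chr1", pos = 1:5, ref = "A", alt = "G",
#'                     qual = 50, depth = c(2, 10, 10, 10, 30))
#' geno <- matrix(1L, 5, 4)
#' filterVariants(VariantTable(sites, geno))
#' @export
filterVariants <- function(x, minQual = 30, minMaf = 0.05,
                           biallelicOnly = TRUE, depthBounds = c(1 / 3, 2)) {
  if (nSites(x) == 0L) stop("empty variant table")
  sites <- variantSites(x)
  keep <- rep(TRUE, nrow(sites))
  removed <- c(qual = 0L, multiallelic = 0L, maf = 0L, depth = 0L)

  okQual <- is.na(sites$qual) | sites$qual >= minQual
  removed["qual"] <- sum(!okQual)
  keep <- keep & okQual

  if (biallelicOnly) {
    okBi <- !grepl(",", sites$alt, fixed = TRUE)
    removed["multiallelic"] <- sum(keep & !okBi)
    keep <- keep & okBi
  }

  maf <- siteMaf(x)
  okMaf <- is.na(maf) | maf >= minMaf
  removed["maf"] <- sum(keep & !okMaf)
  keep <- keep & okMaf

  refMean <- x@meta$refMeanDepth
  if (is.null(refMean)) refMean <- mean(sites$depth, na.rm = TRUE)
  if (is.finite(refMean)) {
    lo <- depthBounds[1] * refMean
    hi <- depthBounds[2] * refMean
    okDepth <- is.na(sites$depth) |
      (sites$depth >= lo & sites$depth <= hi)
    removed["depth"] <- sum(keep & !okDepth)
    keep <- keep & okDepth
  }

  if (!any(keep)) warning("all sites removed by filters")
  out <- subsetSites(x, which(keep))
  out@meta$refMeanDepth <- refMean
  attr(out, "removed") <- removed
  out
}

## minor-allele frequency per site, from haplotypes if present else genotypes
siteMaf <- function(x) {
  if (ncol(x@haplotypes)) {
    f <- rowMeans(x@haplotypes, na.rm = TRUE)
  } else if (ncol(x@geno)) {
    f <- rowMeans(x@geno, na.rm = TRUE) / 2
  } else {
    return(rep(NA_real_, nSites(x)))
  }
  pmin(f, 1 - f)
}

## ---------------------------------------------------------------------------
## Rate maps
## ---------------------------------------------------------------------------

#' Read a fine-scale rate map
#'
#' Two TSV dialects are supported. `"per-snp-interval"`: columns
#' `start end rate` (0-based bp), with each row's end equal to the next
#' row's start, as emitted by per-SNP-interval LD-based estimators.
#' `"fixed-window"`: columns `chrom window_start window_end rate` with
#' possibly overlapping sliding windows (e.g. 10 kb windows at 5 kb step);
#' these are converted to non-overlapping elementary intervals whose rate is
#' the mean of all covering windows.
#'
#' @param path file path (whitespace/tab separated, `#` comments allowed,
#'   optional header).
#' @param dialect `"per-snp-interval"` or `"fixed-window"`.
#' @param chrom chromosome name for the per-snp-interval dialect (which has
#'   no chrom column).
#' @param units unit tag for the returned map.
#' @return a [FineScaleMap-class].
#' @export
readRateMap <- function(path, dialect = c("per-snp-interval",
                                           "fixed-window"),
                        chrom = "chr1", units = "rho/bp") {
  dialect <- match.arg(dialect)
  tab <- read.table(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  ## tolerate a header line
  if (!is.numeric(tab[[if (dialect == "per-snp-interval") 1 else 2]])) {
    tab <- read.table(path, header = TRUE, comment.char = "#",
                      stringsAsFactors = FALSE)
  }
  if (dialect == "per-snp-interval") {
    start <- as.numeric(tab[[1]]); end <- as.numeric(tab[[2]])
    rate <- as.numeric(tab[[3]])
    bad <- which(end <= start)
    if (length(bad))
      stop("non-monotone interval at line ", bad[1],
           ": end <= start (", start[bad[1]], ", ", end[bad[1]], ")")
    gapped <- which(start[-1] != end[-length(end)])
    if (length(gapped))
      stop("intervals not contiguous at line ", gapped[1] + 1,
           ": start != previous end")
    if (any(rate < 0)) stop("negative rate at line ", which(rate < 0)[1])
    FineScaleMap(chrom, c(start, end[length(end)]), rate, units = units,
                 source = path)
  } else {
    chromCol <- as.character(tab[[1]])
    if (length(unique(chromCol)) > 1)
      stop("fixed-window dialect supports one chromosome per file")
    ws <- as.numeric(tab[[2]]); we <- as.numeric(tab[[3]])
    rate <- as.numeric(tab[[4]])
    bad <- which(we <= ws)
    if (length(bad)) stop("non-monotone window at line ", bad[1])
    if (any(diff(ws) <= 0)) stop("window starts must increase, line ",
                                 which(diff(ws) <= 0)[1] + 1)
    if (any(rate < 0)) stop("negative rate at line ", which(rate < 0)[1])
    ## elementary intervals between all window boundaries
    bounds <- sort(unique(c(ws, we)))
    n <- length(bounds) - 1
    mids <- (bounds[-1] + bounds[-(n + 1)]) / 2
    elemRate <- vapply(mids, function(m) {
      covering <- rate[ws < m & we > m]
      if (length(covering)) mean(covering) else NA_real_
    }, numeric(1))
    keep <- !is.na(elemRate)
    ## require contiguity of covered elementary intervals
    runs <- rle(keep)
    if (sum(runs$values) > 1)
      stop("fixed-window input leaves internal gaps in coverage")
    FineScaleMap(unique(chromCol),
                 c(bounds[-(n + 1)][keep], max(bounds[-1][keep])),
                 elemRate[keep], units = units, source = path)
  }
}

#' Write a fine-scale rate map as a per-snp-interval TSV
#'
#' @param map a [FineScaleMap-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeRateMap <- function(map, path) {
  p <- snpPositions(map)
  n <- length(p)
  df <- data.frame(start = p[-n], end = p[-1], rate = intervalRates(map))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## BED / GFF3 / FASTA / TSS / pedigree
## ---------------------------------------------------------------------------

#' Read/write BED intervals
#'
#' Thin wrappers over [rtracklayer::import.bed()] /
#' [rtracklayer::export.bed()]: in-memory `GRanges` are 1-based closed, the
#' files are standard 0-based half-open BED3/BED6.
#'
#' @param path file path.
#' @return `readBed()` returns a `GRanges`.
#' @export
readBed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' @param gr a `GRanges` (optional `name` and `score` metadata columns are
#'   emitted as BED6).
#' @rdname readBed
#' @export
writeBed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read gene annotations and extract TSS records
#'
#' Accepts either a GFF3 file (gene-type features; the TSS is the
#' strand-aware 5' end) or a TSS TSV with columns
#' `gene_id chrom tss strand` (`tss` 0-based bp).
#'
#' @param path annotation file.
#' @return data.frame with columns `gene_id`, `chrom`, `tss` (0-based bp),
#'   `strand`.
#' @export
readTss <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "GFF3")
    gr <- gr[gr$type == "gene"]
    strand <- as.character(GenomicRanges::strand(gr))
    if (any(strand == "*"))
      stop("genes without strand: ",
           paste(head(gr$ID[strand == "*"]), collapse = ", "))
    tss0 <- ifelse(strand == "+", GenomicRanges::start(gr) - 1L,
                   GenomicRanges::end(gr) - 1L)
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
      sprintf("gene%05d", seq_along(gr))
    data.frame(gene_id = ids,
               chrom = as.character(GenomeInfoDb::seqnames(gr)),
               tss = tss0, strand = strand)
  } else {
    tab <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "tss", "strand")
    if (!all(need %in% names(tab)))
      stop("TSS table must have columns: ", paste(need, collapse = ", "))
    tab[need]
  }
}

#' @param tss a TSS data.frame as returned by `readTss()`.
#' @rdname readTss
#' @export
writeTss <- function(tss, path) {
  write.table(tss, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a FAM-style pedigree TSV
#'
#' Columns: `id sire dam sex population`; unknown parents are `0` or `NA`
#' on disk and `NA` in memory.
#'
#' @param path file path.
#' @return `readPedigree()` returns the pedigree data.frame.
#' @export
readPedigree <- function(path) {
  ped <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = c("NA", "0"))
  need <- c("id", "sire", "dam", "sex", "population")
  if (!all(need %in% names(ped)))
    stop("pedigree must have columns: ", paste(need, collapse = ", "))
  ped[need]
}

#' @param ped pedigree data.frame.
#' @rdname readPedigree
#' @export
writePedigree <- function(ped, path) {
  out <- ped
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a GenomeIndex from a FASTA file or DNAStringSet
#'
#' @param x path to a FASTA file, or a [Biostrings::DNAStringSet].
#' @return a [GenomeIndex-class].
#' @export
genomeIndexFromFasta <- function(x) {
  dss <- if (is.character(x)) Biostrings::readDNAStringSet(x) else x
  GenomeIndex(names(dss), Biostrings::width(dss))
}

## ---------------------------------------------------------------------------
## VCF
## ---------------------------------------------------------------------------

#' Write a VariantTable as a minimal VCF
#'
#' Emits a plain-text VCF 4.2 with GT fields (unphased), per-site QUAL and
#' an INFO `DP` carrying the site mean depth. Haplotype-only tables are
#' written as phased pseudo-diploids (haplotypes paired in order).
#'
#' @param x a [VariantTable-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeVcfFile <- function(x, path) {
  sites <- variantSites(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Float,Description=\"Site mean depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"), con)
  if (ncol(x@haplotypes)) {
    nh <- ncol(x@haplotypes)
    if (nh %% 2L) stop("odd haplotype count cannot be written as diploids")
    ids <- sprintf("HAP%03d", seq_len(nh / 2))
    gtxt <- matrix("", nrow(sites), nh / 2)
    for (k in seq_len(nh / 2))
      gtxt[, k] <- paste0(x@haplotypes[, 2 * k - 1], "|",
                          x@haplotypes[, 2 * k])
  } else {
    ids <- colnames(x@geno)
    if (is.null(ids)) ids <- sprintf("S%03d", seq_len(ncol(x@geno)))
    code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    gtxt <- matrix("./.", nrow(sites), ncol(x@geno))
    ok <- !is.na(x@geno)
    gtxt[ok] <- code[as.character(x@geno[ok])]
  }
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ids), collapse = "\t"), con)
  info <- ifelse(is.na(sites$depth), ".",
                 paste0("DP=", format(sites$depth, trim = TRUE)))
  qual <- ifelse(is.na(sites$qual), ".", format(sites$qual, trim = TRUE))
  body <- cbind(sites$chrom, format(sites$pos, scientific = FALSE,
                                    trim = TRUE),
                ".", sites$ref, sites$alt, qual, ".", info, "GT", gtxt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a VCF into a VariantTable
#'
#' Extracts CHROM/POS/REF/ALT/QUAL, the INFO `DP` site depth when present,
#' and GT as alt-allele dosage. Phased pipe-separated genotypes also
#' populate the haplotype matrix.
#'
#' @param path VCF path (plain text or gzipped).
#' @return a [VariantTable-class].
#' @export
readVcfFile <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "DP")))
  sites <- data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                      ref = fix$REF, alt = fix$ALT,
                      qual = suppressWarnings(as.numeric(fix$QUAL)),
                      depth = dp)
  gt <- vcfR::extract.gt(v, element = "GT")
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  num <- function(a) suppressWarnings(as.integer(a))
  geno <- matrix(num(a1) + num(a2), nrow = nrow(gt),
                 dimnames = dimnames(gt))
  hap <- matrix(integer(0), nrow = nrow(sites), ncol = 0)
  if (all(grepl("|", gt[1, ], fixed = TRUE))) {
    hap <- cbind(matrix(num(a1), nrow(gt)), matrix(num(a2), nrow(gt)))
    ## interleave to keep sample pairing
    idx <- as.vector(rbind(seq_len(ncol(gt)), ncol(gt) + seq_len(ncol(gt))))
    hap <- hap[, idx, drop = FALSE]
  }
  VariantTable(sites, geno, hap)
}

## ---------------------------------------------------------------------------
## MEME minimal motif format
## ---------------------------------------------------------------------------

#' Read a PWM from MEME minimal motif format
#'
#' Parses the `MOTIF` / `letter-probability matrix` blocks of the MEME
#' minimal text format, including the `background letter frequencies` line
#' when present. Only the first motif is returned.
#'
#' @param path file path.
#' @param pseudocount pseudocount stored on the returned [PWM-class].
#' @return a [PWM-class].
#' @export
readMemePwm <- function(path, pseudocount = 0.01) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bgLine <- grep("^background letter frequencies", lines, ignore.case = TRUE)
  if (length(bgLine) && bgLine[1] < length(lines)) {
    toks <- strsplit(trimws(lines[bgLine[1] + 1]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    bg <- vals[!is.na(vals)]
    if (length(bg) != 4) bg <- rep(0.25, 4)
  }
  mline <- grep("^MOTIF", lines)
  if (!length(mline)) stop("no MOTIF record in ", path)
  name <- strsplit(trimws(lines[mline[1]]), "\\s+")[[1]][2]
  hline <- grep("^letter-probability matrix", lines)
  hline <- hline[hline > mline[1]][1]
  if (is.na(hline)) stop("no letter-probability matrix in ", path)
  w <- suppressWarnings(as.integer(sub(".*w=\\s*(\\d+).*", "\\1",
                                       lines[hline])))
  rows <- list()
  i <- hline + 1
  while (i <= length(lines) && length(rows) < w) {
    toks <- suppressWarnings(as.numeric(
      strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(toks) == 4 && !any(is.na(toks)))
      rows[[length(rows) + 1]] <- toks
    else if (length(rows)) break
    i <- i + 1
  }
  if (length(rows) != w) stop("expected ", w, " matrix rows, found ",
                              length(rows))
  prob <- do.call(rbind, rows)
  prob <- prob / rowSums(prob)  # guard against rounded rows
  PWM(prob, background = bg, pseudocount = pseudocount, name = name)
}

#' Write a PWM in MEME minimal motif format
#'
#' @param pwm a [PWM-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeMemePwm <- function(pwm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies",
               paste(sprintf("%s %.6f", c("A", "C", "G", "T"),
                             pwm@background), collapse = " "), "",
               paste("MOTIF", pwm@name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       motifLength(pwm))), con)
  writeLines(apply(pwm@prob, 1, function(r)
    paste(sprintf("%.6f", r), collapse = "  ")), con)
  invisible(path)
}
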