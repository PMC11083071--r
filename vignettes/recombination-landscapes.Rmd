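---
title: "Mapping recombination landscapes and characterizing hotspots"
author: "recombMap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping recombination landscapes and characterizing hotspots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recombMap)
```

# Overview

`recombMap` implements a two-scale analysis of meiotic recombination in
livestock genomes, of the kind used to study pig populations:

1. **Broad scale (pedigree-based).** Crossovers are observed directly in
   families: for each focal individual (FID) with genotyped offspring,
   transmission phasing reveals which parental haplotype each offspring
   inherited along the chromosome, and switches in that origin sequence
   are crossovers. Counts per 1 Mb window, averaged over meioses, give the
   meiotic recombination map in cM/Mb, and per-FID averages (ACM, the
   average number of crossovers per meiosis) support contrasts between
   populations and sexes.
2. **Fine scale (population-based).** LD-based estimators provide a
   per-SNP-interval population-scaled recombination rate
   (rho = 4 Ne r per bp). On such a map, recombination hotspots are runs
   of consecutive intervals whose rate strictly exceeds 10 times the
   chromosomal mean, and coldspots are runs strictly below one tenth of
   it. Called intervals are then characterized: GC content and nucleotide
   diversity against size-matched random fragments, proximity to
   transcription start sites (TSS) against a random-point permutation
   null, and enrichment of a zinc-finger (PRDM9-like) DNA-recognition
   motif in hotspot versus coldspot sequences.

The package operates on standard Bioconductor containers (`GRanges`,
`DNAStringSet`) plus small S4 classes for the domain objects
(`FineScaleMap`, `WindowMap`, `MeiosisSet`, `VariantTable`, `PWM`,
`SimConfig`, `TruthSet`). Because the kind of pedigree/WGS data this
analysis needs is rarely public, a first-class synthetic-data module
generates every input with a recorded ground truth; all validation is
against that truth or against independent oracles.

# The models and procedures

## Variant filtering

Sites are retained when site quality >= 30, exactly one alternate allele,
minor-allele frequency >= 0.05, and site mean depth within one third to
twice the population mean depth. All retention thresholds are inclusive.
Two conventions deserve note:

* The common `max-maf < 0.05` phrasing of the frequency filter is
  ambiguous as a vcftools invocation (taken literally it would *keep*
  only rare variants); `filterVariants()` implements the evident intent,
  removing minor-allele frequencies below 5%.
* The depth filter is defined relative to a mean. To make the operation
  idempotent (an invariant the test suite enforces), the reference mean
  is computed once from the incoming table and recorded in the result's
  metadata; re-filtering reuses it. This mirrors the usual practice of
  computing the mean on the full callset.

## Crossover detection

`phaseByTransmission()` deduces, at every marker where the FID is
heterozygous, which allele was transmitted to each offspring (forced when
the mate is homozygous, or when the offspring is homozygous). The FID's
haplotype labelling is assembled marker by marker by a minimum-switch
majority vote across offspring — a deliberate, simple stand-in for
full-pedigree phasing tools, validated only against simulation truth.
`detectCrossovers()` then emits a crossover at each boundary between
maximal runs of consistent origin, requiring `minSupport` (default 3)
consecutive informative markers on both sides; shorter flips are treated
as genotyping errors. Close double crossovers (midpoints < 3 Mb apart in
one meiosis) are unreliable and are masked: both events are removed, the
spanned region is treated as missing, and detection is re-run once
(`detectAndQc()`).

Two consequences of this design are worth stating because they bound
what end-to-end recovery can achieve. With chip-like allele frequencies
(drawn U(0.1, 0.9)) roughly one third of markers are informative per
meiosis, so (a) crossovers within about three informative-marker gaps of
a chromosome end are undetectable, and (b) genuine crossover pairs with
fewer than `minSupport` informative markers between them cancel. Both
channels together cost roughly 3-4% of true events at 50 kb marker
spacing on a 50 Mb chromosome; the detector itself, given fully
informative origin sequences, recovers >= 99% (asserted in the test
suite). The second channel concerns exactly the close pairs the 3 Mb QC
is designed to distrust.

## Window rates by Monte-Carlo allocation

A detected crossover is only localized between two informative markers.
`estimateWindowRatesMc()` treats its position as uniform on that interval:
per replicate, positions are drawn and counted into 1 Mb windows; counts
are averaged and scaled to cM/Mb as `100 * count / (meioses * Mb)`. This
realizes the Poisson/Monte-Carlo estimation idea as the Monte-Carlo
expectation of window counts (the Poisson MLE), without any smoothing —
a declared reading, since the underlying estimator's formulas are not
fully specified by its users. Crossover mass is conserved exactly: summing
`rate x Mb / 100` over windows returns the mean crossovers per meiosis.
The last partial window of a chromosome uses its true length.

## Hotspot and coldspot calling

`callHotspots()` follows a three-stage filter, with the chromosomal mean
rate length-weighted by default (per-SNP intervals have wildly unequal
lengths; an unweighted flag is provided for sensitivity analysis):

1. candidates are maximal runs of intervals with rate strictly
   > 10 x mean, spanning first to last SNP of the run;
2. candidates spanning fewer than 2 SNPs **or** more than 5 kb are
   dropped (read as two independent discard rules — a literal conjunction
   would retain 6 kb single-SNP spans that the filter plainly intends to
   remove);
3. surviving candidates separated by at most 2 intervening SNPs and a gap
   of at most 1 kb are merged transitively. Merging happens after the
   length filter, so merged calls may exceed 5 kb; `mergedFrom` records
   how many candidates were absorbed.

Coldspots are maximal runs strictly below mean/10 spanning at least 3
SNPs, with no length cap or merging. Both thresholds are strict
inequalities, and calls are invariant to rescaling all rates by a
positive constant. The implementation is held equal, call for call, to an
independent brute-force oracle that enumerates runs and applies the rules
literally (500 random maps in the acceptance suite).

## Interval characterization

* **GC**: `(G + C) / (A + C + G + T)` per interval, ambiguous bases
  excluded from the denominator; all-ambiguous intervals are missing.
* **Nucleotide diversity**: per segregating site
  `pi = 2 j (n - j) / (n (n - 1))` over `n` non-missing haplotypes with
  `j` alternate copies; interval pi divides the summed site values by the
  interval's physical length (the convention of windowed diversity
  outputs), not by the genotyped-site count.
* **Matched nulls**: 1000 sets of random fragments matched per fragment
  to the observed lengths, placed uniformly (chromosomes weighted by
  placeable length) outside an optional exclusion mask, by rejection
  sampling with an explicit failure after 10,000 attempts.
* **Significance**: empirical p-values use the add-one convention
  `(r + 1) / (n + 1)`, which cannot return zero; two-sample contrasts use
  the Wilcoxon rank-sum test (independent interval sets, so rank-sum
  rather than signed-rank), exact for small untied samples and
  normal-approximated with tie correction otherwise.

## TSS proximity

TSS windows span +/- 3 kb around the strand-aware 5' gene end, clipped at
chromosome bounds, duplicates collapsed. A hotspot counts as overlapping
when its midpoint (floor of the mean of the half-open bounds) lies in at
least one window, bounds inclusive. The null draws sets of genome-wide
uniform points; the number of points per set defaults to the observed
hotspot count — the only choice making observed and null counts
commensurable given conflicting conventions for the null-set size (200 vs
1000 points appear in common practice); 1000 sets are used. The empirical
p-value in the direction of the observed deviation is the recommended
statistic; because that direction is chosen after seeing the data, the
value is one-sided post hoc — double it for a pre-registered two-sided
claim (the test suite verifies the corresponding 2-alpha validity
bound); a one-sample t-test of the null values against the observed
count is reported alongside because permutation-density figures are often
annotated with it, but with 1000 null values it is extremely liberal and
should not be interpreted as the test.

## Motif enrichment

A PWM (L x 4 probabilities, MEME minimal format I/O) is scanned in
log-odds form, `log2(((p + 0.01 bg) / 1.01) / bg)`, over every offset of
both strands; windows containing ambiguous bases are skipped, and a
sequence's score is its best window (bits). The default background is
uniform; a GC-aware background estimated from coldspot sequences
(`backgroundFromSequences()`) is the conservative alternative when
classes differ in GC. Enrichment of hotspot over coldspot scores is
tested one-sided by rank-sum (default) or, dichotomized at a score
threshold, by Fisher's exact test — the Fisher branch is held equal to
the hypergeometric closed form in the tests. No attempt is made to
replicate any specific enrichment tool bit for bit; the 0-order
background and pseudocount are declared defaults. Scanning itself runs
through `Biostrings::PWMscoreStartingAt` on the package's log-odds
matrices.

# The synthetic-data generators

`simConfig()` fixes the study conditions; every generator derives a child
seed from the master seed by a stable string hash (`stageSeed()`), so
adding a stage never perturbs another stage's draws, and all generators
are byte-deterministic given the seed.

* **Fine map** (`simulateFineMap()`): SNP positions with exponential
  500 bp spacing on a 10 Mb chromosome; 20 hotspots at 50-fold and 10
  broad coldspots at 0.02-fold the background rate; every interval
  multiplied by lognormal noise (sdlog 0.3). An interval adopts a planted
  fold when its midpoint lies inside the plant. Hotspot widths are drawn
  from 2000-3200 bp: wide enough that a plant spans several SNP intervals
  at the 500 bp spacing (the real-data geometry is ~9 SNPs per ~1.26 kb
  hotspot at ~138 bp map resolution), yet below the 5 kb filter cap even
  with boundary-interval overhang. Features planted below the map's
  resolution are invisible to any caller — the generator's job is to
  emulate resolvable structure.
* **Pedigree panel** (`simulatePedigreeMeioses()`): 30 FIDs x 10
  offspring at 50 kb marker spacing, marker allele frequencies
  U(0.1, 0.9); crossover counts Poisson with the map's genetic length as
  mean (no interference — close double crossovers are rare and the QC
  masks them; an obligate-crossover flag exists, default off); positions
  by inverse CDF of the cumulative map; one observed gamete per meiosis.
  Each offspring has its own unrelated mate (multi-mate pig pedigrees),
  transmitted without recombination so the truth (FID crossovers) is
  complete and mates never satisfy the FID rule; genotype errors are
  independent dosage flips at rate 0.002 by default. The pipeline drives
  this panel with the noiseless fine-map landscape scaled to 1 Morgan —
  the genetic length of a typical pig chromosome, standing in for a full
  chromosome at desk scale.
* **Sequences** (`simulateSequences()`): i.i.d. bases at GC 0.4296
  genome-wide and 0.4646 inside hotspots (the magnitudes reported for
  the pig genome); one PWM consensus planted per hotspot with
  probability 0.8 and per coldspot with probability 0.05, random strand
  and offset, recorded in the truth.
* **Variants** (`simulateVariants()`): segregating sites as a Poisson
  process with densities 0.0141/bp in hotspots and 0.0096/bp in
  coldspots; these follow from targeting interval diversities of 0.00291
  and 0.00198 under the neutral 1/j allele-frequency spectrum with
  n = 72 haplotypes (36 diploids), for which the expected per-site pi is
  1/H(n-1) ~ 0.207. The 1/j spectrum keeps pi proportional to site
  density without needing a coalescent simulator; no LD is generated
  (LD-based estimation itself is out of scope).
* **Annotations** (`simulateAnnotations()`): 80 TSS (8 genes/Mb, random
  strand) and 72 peaks of 1648 bp (promoter-mark-like width), each peak
  centred within +/- 3 kb of a random TSS with probability 0.635.

Two desk-scale artifacts of this geometry are worth knowing when reading
the pipeline's summary numbers. First, the 3 Mb double-crossover QC rule
is kept at its real-genome value, but on a compressed 10 Mb chromosome
carrying 1 Morgan it spans 30% of the chromosome, so a large share of
genuine double crossovers is masked and the pipeline's ACM lands well
below the planted 1.0 (the QC rule itself is validated separately on
50 Mb fixtures where its footprint is realistic). Second, the planted
landscape is flat at the broad scale — hotspots are kilobase features
that barely move a 1 Mb window's mass — so the pedigree-vs-truth window
correlation on pipeline output is close to zero by construction; window
recovery is instead validated on a map with genuine 10-fold 1 Mb-scale
variation, where the Monte-Carlo estimator reaches Spearman ~0.95.

What the generators deliberately do **not** emulate: linkage
disequilibrium among the population variants, crossover interference,
ascertainment structure of real chips beyond the frequency range, hotspot
avoidance of TSS (hotspots are planted uniformly, so the TSS test's
synthetic result is null — depletion is exercised by constructed
fixtures), and sequence composition beyond 0-order GC. Passing tests
therefore demonstrate correctness of the estimators and callers on data
satisfying their assumptions, not performance on real pig data.

# Numerical and design choices

* Coordinates: `GRanges` are 1-based closed (Bioconductor); BED files are
  0-based half-open via `rtracklayer`; VCF positions 1-based;
  `FineScaleMap` SNP positions 0-based. One conversion layer
  (`io` functions) touches coordinates.
* Hotspot spans run from the first to the last SNP of the qualifying run
  and are emitted half-open at `last + 1`.
* The double-crossover distance is measured midpoint to midpoint (the
  reference points are not standardized elsewhere); masking iterates
  leftmost-pair-first until no violation remains.
* ACM contrasts use a one-way ANOVA F-test per population pair within
  sex; groups with fewer than two FIDs are skipped with a warning;
  zero-variance pairs return F = 0, p = 1 rather than NaN.
* Window correlations (`mapCorrelation()`) are Spearman by default —
  rank-based and therefore unit-free, so rho-scaled and cM/Mb maps can be
  compared without an Ne assumption (a scalar converter `scaleRates()`
  exists for display); windows missing in either map are excluded rather
  than imputed as zero; at least 3 shared windows are required.
* Degenerate inputs are decided, not accidental: an all-zero map has mean
  0 and strict inequalities yield no calls; a fully tied rank-sum returns
  p = 1; a zero-variance permutation null returns t-test p of 0 or 1 by
  agreement with the observed value while the empirical p remains valid.
* Test problem sizes: the suite validates at 10-50 Mb chromosomes,
  300-1000 meioses, 100-200 sequences per class and 500-replicate
  calibrations — sizes chosen so every property is measurable with
  comfortable Monte-Carlo margins on a single CPU.

# Known limitations

* Transmission phasing is a stand-in for full-pedigree phasing tools; it
  uses no linkage information at ambiguous markers, so per-meiosis
  informativeness is bounded by single-marker logic (about one third of
  chip markers), with the end-censoring consequences quantified above.
* The hotspot caller is the published filtering heuristic, not a
  composite-likelihood hotspot scan; no cross-population hotspot sharing
  is implemented.
* pi uses physical interval length as denominator; intervals with no
  callable sites are indistinguishable from truly monomorphic ones.
* The permutation t-test is reported for comparability but is not a
  calibrated test; use the empirical p.
* Sex chromosomes are out of scope throughout.
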