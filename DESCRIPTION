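Package: recombMap
Title: Pedigree and Population Recombination Landscapes with Hotspot
    Characterization
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for building and comparing meiotic recombination maps in
    livestock pedigrees and fine-scale historical (LD-based) recombination
    maps from population data. Detects crossovers by transmission phasing in
    half-sib families, applies close-double-crossover quality control, and
    estimates 1 Mb window rates by Monte Carlo allocation. Calls
    recombination hotspots and coldspots from per-SNP-interval rate maps by
    a fold-over-chromosomal-mean filter, characterizes interval GC content
    and nucleotide diversity against size-matched random-fragment nulls,
    tests hotspot proximity to transcription start sites with a random-point
    permutation null, and tests PRDM9-motif (PWM) enrichment in hotspot
    versus coldspot sequences. A synthetic-data module generates every input
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    vcfR,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
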