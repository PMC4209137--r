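Package: meioscan
Title: Crossover Detection and Recombination Landscapes in Hypervariable
    Haploid Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects meiotic crossovers in haploid fungal crosses from
    aligned parental and offspring genomes, localizes them to crossover
    regions (CORs) bounded by interparental marker sites, and tests the
    recombination landscape against matched nulls: a length-biased
    exponential null for COR lengths, identity-tract-matched permutation
    tests for exon/intron enrichment, nucleotide diversity, GC and
    minor-allele-frequency windows around CORs, Tajima's D, and linkage
    disequilibrium across crossover sites.  Includes a synthetic-cross
    generator for hypervariable haploid genomes (two parents at ~14%
    divergence, population panels, recombinant offspring with recorded
    breakpoints) used for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
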