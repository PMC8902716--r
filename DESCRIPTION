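Package: dioscan
Title: Population-Genomic Scans for Dioecious Plant Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, simulation-testable pipeline for the population
    genomics of dioecious plants with young sex chromosomes. Delimits a
    sex-determination region (SDR) by intersecting five evidence tracks
    (F1 co-segregation contig density, sex-association scores, male-specific
    SNP density, male/female Fst, and male/female Tajima's D ratio) with
    contig-terminal boundary snapping; scans for domestication sweeps with
    windowed wild/cultivated diversity ratios and a folded-SFS generalized
    likelihood ratio; scans for introgression with Patterson's D (weighted
    block jackknife) and windowed fd_M; and dates X/Y gene pairs and LTR
    retrotransposons via NG86 Ka/Ks and Kimura two-parameter distances with
    T = Ks/2r. Includes a seeded generator of labeled dioecious-population
    datasets (Balding-Nichols structure, hemizygous Y-linked markers, F1
    crosses, sweeps, admixture) so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse
Config/testthat/edition: 3
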