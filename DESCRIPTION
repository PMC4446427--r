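Package: homotract
Title: Position-Resolved Mutational Patterns in Mononucleotide Repeats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans reference sequences for maximal mononucleotide repeats
    (A-tracts and G-tracts) with flanking context, assigns SNVs and indels
    from VCF call sets to tract positions on the purine strand, classifies
    single-base length changes as replication slippage versus general indels
    by an apply-and-rescan rule, and computes the normalized positional
    mutation statistics (F SNV, per-position substitution spectra,
    flank-direction bias, slippage and indel fractions, insertion-junction
    matrices, dataset equalization). Also provides nucleosome dyad-distance
    profiling with strand-orientation ratios, local-regression smoothing and
    periodogram-based periodicity estimation, base-pair-step flexibility
    statistics (V_step, groove widths, water-bridge occupancy) from tabulated
    trajectories, and a synthetic-data generator with truth tables so every
    stage is verifiable without genome-scale downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    MASS,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
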