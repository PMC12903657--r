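Package: popgenviz
Title: Publication-Ready Visualization of Population-Genomic Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A unified toolkit for the six figures population geneticists
    draw most often from standard pipeline outputs: per-chromosome SNP
    density heatmaps from PLINK marker maps, runs-of-homozygosity (or CNV)
    tracks with shared-region detection, genomic-relationship heatmaps
    with population-level averaging, 2D/3D PCA scatter plots, admixture
    stacked barplots with dominant-ancestry sorting, and Manhattan plots
    with automatic cumulative genomic coordinates. All preprocessing
    (binning, interval merging and sweep-line coverage, pair averaging,
    coordinate accumulation, ancestry sorting) is automated, every input
    dialect is validated with row-level diagnostics, and figures export
    to common bitmap and vector formats. Includes seeded synthetic-data
    generators for every input dialect and a subcommand-style dispatch
    usable from the shell.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    ggplot2,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
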