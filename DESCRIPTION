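Package: evokit
Title: Growth Fitness, Mutation Localization and Chromosomal Periodicity
    for Bacterial Experimental Evolution
Version: 0.1.0
Authors@R:
    person("Evokit", "Developers", email = "evokit@example.org",
           role = c("aut", "cre"))
Author: Evokit Developers [aut, cre]
Maintainer: Evokit Developers <evokit@example.org>
Description: Analysis toolkit for serial-transfer experimental evolution of
    genome-reduced bacteria. Estimates exponential growth rates and carrying
    capacities from plate-reader OD600 curves using a windowed-rate rule,
    counts evolutionary generations from serial-transfer logs, tests for
    locational bias of fixed mutations relative to genome-reduction scars by
    a 1000-replicate randomization scheme with Welch's t-test, analyses
    chromosomal periodicity of transcriptomes (genomic binning, moving-average
    smoothing, periodogram, Fisher's g test, fixed-period sinusoid fit), and
    computes binomial enrichment statistics with Bonferroni correction. A
    synthetic-data generator emulates the statistical structure of the real
    inputs (circular reduced genome, scar junctions, logistic growth curves,
    sinusoidal expression signal) so the full pipeline builds and tests
    without any sequencing download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
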