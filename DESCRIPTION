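Package: larvascan
Title: Pool-Seq Selection Scans for Single-Generation Larval Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects viability-associated and size-associated SNPs from pooled
    allele-count time series collected over a single generation of bivalve
    larval cohorts reared in a factorial (NC-II) cross. Implements the pooled
    allele-frequency calculus, depth and zero-recovery filtering, per-marker and
    per-contig chi-square contingency scans with per-replicate alpha = 0.05/nHet
    thresholds and q-value FDR control, consistent-trend marker selection, a
    Monte-Carlo sampling-noise ("chance of drift") null, heterozygosity and
    sequence-divergence summaries, and a synthetic-data generator that emulates
    the cross design, type-III larval survivorship, stage-specific viability and
    size selection, and pooled sequencing, so that every stage of the pipeline
    is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
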