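Package: kdmr
Title: Kernel-Smoothed Detection of Differentially Methylated Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls differentially methylated regions (DMRs) and variably
    methylated regions (VMRs) from array-style DNA methylation data.
    Per-CpG empirical-Bayes moderated statistics are squared and smoothed
    along each chromosome with a Gaussian kernel; the smoothed statistic is
    modelled under the null as a scaled chi-squared variable by Satterthwaite
    moment matching, giving per-site P values that are FDR-corrected and
    agglomerated into ranked regions. Includes probe-level quality filters,
    a simulator that plants DMRs of known effect size into a synthetic
    reduced-representation methylome, and a nucleotide-resolution
    precision-recall evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    stats,
    utils
Suggests:
    limma,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
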