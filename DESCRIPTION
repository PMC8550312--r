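Package: qsipr
Title: Genome-Resolved Quantitative Stable-Isotope Probing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-taxon 13C atom percent excess (APE) from
    density-fractionated metagenome coverage using the quantitative
    stable-isotope probing (qSIP) model of isotope substitution in DNA,
    determines a data-driven labeling detection threshold by segmented
    (breakpoint) regression on the rank-APE curve with a Davies test for
    significance, and estimates taxon-specific gross and net growth rates
    on labeled carbon under a linear growth model. Includes a forward
    simulator of CsCl gradient fractionation (taxa with known GC content,
    abundance, and isotope enrichment, Gaussian density spreading,
    fraction binning, and multinomial sequencing noise) so every stage of
    the pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
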