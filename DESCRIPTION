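Package: lampdx
Title: Diagnostic SNP Discovery and Allele-Specific LAMP/CAPS Assay Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing species-diagnostic molecular assays from
    DNA-barcode alignments. Screens species-labelled alignments for fixed
    interspecific SNPs via per-site intra- and inter-specific nucleotide
    diversity, builds base-preference matrices, predicts in-silico CAPS
    (restriction digest) markers with degenerate-site scanning, enumerates and
    ranks allele-specific LAMP loop primers by a mismatch position/type
    discrimination score, and provides copy-number arithmetic, Cq
    standard-curve fitting, delta-Cq analysis, a seeded LAMP kinetics
    simulator and the dual-reaction species-identification decision engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
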