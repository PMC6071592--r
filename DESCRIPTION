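Package: phantomepi
Title: High-Order Linkage Disequilibrium and Phantom Statistical Epistasis
    in Inbred Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies second-order (high-order) linkage disequilibrium
    between pairs of genotyped SNPs (predictors) and hidden polymorphisms
    (targets) in inbred populations via four bi-allelic pseudomarkers,
    classifies and extrapolates strong triplets genome-wide (cis-cis,
    cis-trans, trans-trans), and runs two-stage two-locus statistical
    epistasis scans (OLS scan, then a kinship-corrected mixed-model refit)
    to demonstrate how statistical epistasis can emerge from high-order
    linkage disequilibrium rather than functional gene interaction.
    Includes generators for synthetic inbred populations (haplotype
    sampling, founder-mosaic genomes with distance-decaying LD, and a
    complex multi-allelic locus scenario) so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
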