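Package: breedwatch
Title: Monitoring Short-Term Selection Against Disease Alleles in Closed Breed Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and monitor short-term artificial selection
    against a disease allele in a closed breed population while tracking
    inbreeding and genetic diversity. Implements a sex-structured
    Wright-Fisher drift null with empirical p-values, per-SNP Weir-Cockerham
    F_ST scans, extended haplotype homozygosity (EHH) decay, consecutive-run
    detection of runs of homozygosity with F_ROH summaries, KING-robust
    kinship pruning, principal component analysis, neighbor-joining trees on
    p-distance, Nei's standard genetic distance, and linkage-disequilibrium
    based contemporary effective population size. Includes a pedigree-based
    synthetic cohort generator emulating a bottlenecked closed breed so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    generics,
    ape,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
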