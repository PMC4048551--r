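Package: blockclock
Title: Dating Admixture from Introgressed Ancestry Block Sizes
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for distinguishing recent from ancient admixture between
    two divergent source populations using phased SNP haplotypes. Provides
    SNP-array quality filters and X-linked sex assignment, a two-donor-panel
    haplotype-copying hidden Markov model for local ancestry inference
    (chromosome painting), conversion of ancestry posteriors into
    introgressed-block tracks, the scaled block size (SBS) statistic for
    comparing the timing of admixture across individuals and groups,
    classification of recent hybrids against known-hybrid standards, and
    bootstrap and permutation tests for chromosome-level deviations in
    ancestry proportions. A built-in admixture simulator (divergent donor
    panels, single-pulse admixture, forward Wright-Fisher with recombination)
    supplies ground-truth ancestry tracts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
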