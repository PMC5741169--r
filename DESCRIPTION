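Package: yyhap
Title: Yin/Yang Haplotype Architecture of Phased Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the block structure of common haplotypes in
    phased diploid cohorts. Builds genomic segments of 50 adjacent frequent
    variants (minor allele frequency above 0.25), groups near-identical
    haplotypes into common haplotypes, detects mutually exclusive Yin/Yang
    haplotype pairs, and decomposes intermediate ("Mosaic") haplotypes into
    the minimal number of Yin/Yang pieces. Polarizes alleles with ancestral
    annotations, deduces fully ancestral haplotypes and their continental
    distribution, and compares common haplotypes against an archaic hominin
    diplotype. Includes a forward-time diploid simulator (permanent-pair
    mating, truncation selection, infinite-sites mutation, crossover
    recombination) for testing whether abundant frequent variants and
    Yin/Yang pairs can arise in a single panmictic population or require the
    admixture of long-separated lineages, closed-form calculators for the
    associated fixation-clock arithmetic, and a synthetic-data generator
    with exact planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
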