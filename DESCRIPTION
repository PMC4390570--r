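Package: wqscan
Title: Selection Mapping and Genomic Diversity in Recurrent-Selection Breeding Populations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time simulation of recurrent-selection breeding
    protocols (selfing, family screening, truncation selection, bulk-entry
    recombination) used to calibrate drift-null significance thresholds for
    SNP-wise Fst selection mapping between selection cycles; genome-wide gene
    diversity (expected heterozygosity) scans with region-level reduction
    summaries; and the quantitative-genetic layer of such programs: family
    variance components with broad-sense heritability by REML, a VanRaden
    genomic relationship matrix, G-BLUP genomic heritability via
    eigen-rotation REML, and a mixed-model association scan. A synthetic-data
    generator emulates multi-cycle family-structured genotypes and phenotypes
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
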