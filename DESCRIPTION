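Package: haplorec
Title: Sliding-Window Haplotype Mapping of Recessive Fertility Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Haplotype-based association mapping of recessive quantitative
    trait loci from phased SNP genotypes, built around the workflow used to
    map male-fertility loci in dairy cattle. Provides a sliding-window
    haplotype scan under additive and recessive inheritance with principal
    component correction and conditional covariates, a genomic relationship
    matrix and Haseman-Elston variance check, carrier-compatibility
    fine-mapping of sequence variants, derivation of a non-return-rate
    fertility phenotype via Henderson's mixed-model equations, semen-quality
    filtering and sperm-morphology trait construction, and a synthetic
    breeding-population generator that exercises the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
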