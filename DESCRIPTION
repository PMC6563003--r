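Package: canidmorph
Title: Genotype-Based Prediction of Coat Color and Ear Morphology in Dogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for known-site genotyping and Mendelian phenotype
    inference at the canine external-morphology loci (A-, B-, D-, E-, K-
    and S-locus coat-color variants plus two ear-carriage variants near
    MSRB3). Provides a curated 16-site variant panel on CanFam3.1, a
    run-length (CIGAR-style) codec for length-polymorphism alleles, readers
    and writers for genotype tables and VCF restricted to panel sites, a
    deterministic epistatic rule engine that predicts coat color and ear
    phenotype from multi-locus genotypes, cross-population allele
    concordance and fixed-difference reporting, and a Hardy-Weinberg
    cohort simulator for testing every stage without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
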