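Package: pgxcohort
Title: Star-Allele Calling, Phenotype Prediction and Gene-Drug Risk
    Summaries for Pharmacogenomic Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for population-scale pharmacogenomics: assign star
    alleles to phased haplotypes by defining-variant matching, estimate
    whole-gene copy number from normalized read depth, translate
    diplotypes to predicted metabolizer phenotypes (translation tables,
    the CYP2D6 activity-score sum, and warfarin dose-category rules for
    CYP4F2/VKORC1), classify phenotypes against EHR priority risk
    notation, cross-reference medication records with PharmGKB evidence
    level 1A drug-gene pairs, and summarize haplotype, diplotype and
    phenotype frequencies. A seeded synthetic-cohort generator produces
    phased VCF, read-depth and medication inputs with known truth under
    Hardy-Weinberg sampling, so the whole pipeline is testable without
    access to restricted cohort data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
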