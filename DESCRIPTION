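Package: ImputeAccuracy
Title: Assessment and Pre-Imputation Prediction of SNP Genotype
    Imputation Accuracy in Multi-Breed Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to measure and to predict the accuracy of SNP genotype
    imputation in structured livestock populations genotyped on nested
    panel densities.  Provides panel masking against a truth set, chip-style
    quality control (MAF, call rate, Hardy-Weinberg, per-animal call rate),
    VanRaden genomic relationships with top-k relationship summaries,
    Mendelian-inconsistency (opposing-homozygote) profiles, a deterministic
    window-haplotype reference imputer plus a major-allele baseline with
    one- and two-step orchestration, concordance-rate and allelic r-squared
    evaluation with MAF-binned and chromosome-end profiling, and a
    pre-imputation predictor that flags animals expected to impute poorly
    from their low-density Mendelian-inconsistency profile.  A pedigree
    gene-dropping simulator generates multi-breed populations with nested
    panels so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'genetic-map.R'
    'breed-plan.R'
    'simulate.R'
    'io-plink.R'
    'io-vcf.R'
    'io-pedigree.R'
    'qc.R'
    'panels.R'
    'relatedness.R'
    'mds.R'
    'impute-baseline.R'
    'impute-window.R'
    'impute-two-step.R'
    'external-formats.R'
    'accuracy.R'
    'scenario.R'
    'predict.R'
    'utils.R'
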