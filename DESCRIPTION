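Package: mmherit
Title: Moment-Matching Estimation of SNP Heritability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Closed-form (Haseman-Elston-family) moment-matching estimation
    of SNP heritability from a genomic relatedness matrix, designed for
    biobank-scale phenome scans. Builds the GRM from PLINK binary genotypes
    with optional genomic-region exclusion, removes covariates by implicit
    projection while streaming the GRM in column blocks, converts estimates
    for binary traits to the liability scale, and provides trait
    preprocessing, sex/age/socioeconomic stratification with difference and
    trend tests, an effective-number-of-tests multiple-testing correction,
    and a synthetic genotype/phenotype simulator with vec-OLS and ReML
    oracles for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
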