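Package: fhetiology
Title: Monogenic and Polygenic Etiology Attribution in Primary
    Hypercholesterolemia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for attributing primary hypercholesterolemia to a
    monogenic, polygenic, or unexplained etiology and for quantifying the
    overlap between genetic etiology and the familial-hypercholesterolemia
    phenotype. Includes cohort selection with secondary-cause exclusion,
    statin-adjusted LDL-C imputation and age/sex percentile strata, Dutch
    Lipid Clinic Network scoring, an ACMG/AMP evidence-combining rule
    engine for rare variants in LDLR, APOB and PCSK9, a 12-SNV weighted
    polygenic score, genotype-phenotype cross-tabulation with
    variance-explained regression, and a synthetic cohort generator with
    Hardy-Weinberg genotypes for end-to-end testing without protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
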