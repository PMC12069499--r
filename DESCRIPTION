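Package: triopoe
Title: Parent-of-Origin Effect Analysis in Parent-Offspring Trio Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating heritability and parent-of-origin effects
    on quantitative traits in parent-offspring trio cohorts with serial
    offspring measurements. Implements mid-parent and parent-specific
    regression models with a Wald Z test for the maternal-paternal
    coefficient difference, longitudinal mixed-effect models with family and
    repeated-observation random intercepts, trio-based assignment of the
    parental origin of offspring alleles with Mendelian-error detection and
    Hardy-Weinberg quality control, and allele-origin association models
    fitted by estimating equations with cluster-robust standard errors. A
    forward simulator generates trio cohorts with known maternal, paternal
    and imprinted genetic effects so that every stage of the pipeline can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    sandwich,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
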