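Package: multiprs
Title: Multi-Polygenic-Score Analysis of General and Specific Child Psychopathology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how polygenic risk scores (PRSs) from many
    discovery GWASs relate to general and domain-specific psychopathology in
    children across cohorts. Implements clumping-and-thresholding (C+T)
    polygenic scoring from GWAS summary statistics with QC and allele
    harmonization, bifactor measurement-model fitting with regression
    (Thurstone) factor scores, per-cohort separate and mutually adjusted PRS
    regressions with incremental R-squared, random-effects meta-analysis
    combining a DerSimonian-Laird heterogeneity estimate with the Han-Eskin
    RE2 likelihood-ratio test, the Li-Ji effective number of independent
    tests, Clogg coefficient-difference z-tests, and repeated k-fold
    cross-validated incremental R-squared for multi-PRS prediction. A
    synthetic-data module generates LD-blocked genotype dosages, discovery
    summary statistics for genetically correlated traits, and
    bifactor-structured symptom subscales with known ground truth, so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), metafor, jsonlite, withr
Config/testthat/edition: 3
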