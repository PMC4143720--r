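Package: ltow
Title: Optimally Weighted Rare-Variant Association Tests for Longitudinal Phenotypes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Region-based association testing between sets of rare and common
    genetic variants and quantitative phenotypes measured at multiple time
    points. Implements L-TOW, a longitudinal extension of the test of an
    optimally weighted combination of variants (TOW): a mixed linear model with
    a between-time-point correlation structure is fitted under the null,
    phenotypes, covariates and genotype dosages are whitened with the inverse
    square root of the fitted covariance, and the optimally weighted score-type
    statistic is evaluated by permutation of the whitened residuals. Includes
    the single-time-point TOW baseline, readers and writers for dosage and
    longitudinal phenotype tables, a region-scan driver, and a simulation
    engine for type-I-error calibration, power comparison and
    variance-component recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, graphics
Suggests: testthat (>= 3.0.0), optparse, jsonlite, VariantAnnotation
Config/testthat/edition: 3
biocViews: StatisticalMethod, GenomeWideAssociation, Genetics,
    VariantAnnotation, Software
RoxygenNote: 7.3.3
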