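Package: crossmet
Title: Cross-Species Untargeted Metabolomics Association and Phenotype
    Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for untargeted LC-HRMS metabolomics analysis across
    species: feature-table preprocessing (blank filtering, half-minimum
    imputation, detection filtering, generalized log transformation,
    location-scale batch standardisation), metabolome-wide association
    testing (covariate-adjusted linear regression, Welch t tests, two-way
    ANOVA with interaction and Tukey HSD), adduct/isotope m/z annotation
    against a compound library with ppm tolerance and confidence levels,
    permutation-based pathway enrichment on putative KEGG annotations,
    direction-concordant cross-species metabolite overlap, Seahorse
    extracellular-flux respiration-state derivation, and Kaplan-Meier
    survival summaries. Includes a synthetic-data module that emulates a
    three-group human cohort with a continuous cerebrospinal-fluid
    biomarker outcome and factorial Caenorhabditis elegans experiments,
    with ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    survival,
    car
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
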