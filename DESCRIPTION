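Package: mwasdbs
Title: Metabolome-Wide Association Study Pipeline for Newborn Dried Blood
    Spots
Version: 0.1.0
Authors@R: person("mwasdbs", "maintainers", role = c("aut", "cre"),
    email = "maintainers@example.org")
Description: An untargeted LC-HRMS metabolome-wide association study (MWAS)
    workflow for archived newborn dried blood spots: feature-table quality
    control (replicate CV, replicate Pearson correlation, missingness
    filters), median replicate summarization, log2 transformation, per-batch
    median centering, auto-scaling and k-nearest-neighbour imputation;
    biomarker-based maternal smoking classification from cotinine and
    hydroxycotinine ion intensities; covariate residualization; NIPALS
    PLS-DA with VIP feature selection and fold changes; per-feature logistic
    regression with Benjamini-Hochberg FDR; adduct-based metabolite
    annotation at 5/10 ppm tolerances; and mummichog-style pathway
    enrichment using the EASE score with a gamma-modelled permutation null.
    Includes a seeded synthetic-data generator that emulates the study
    design (triplicate injections, batches of 40, intensity-dependent
    missingness, overlapping exposure indicators, planted log2 effects and a
    planted enriched pathway) so the full pipeline is testable without
    access-restricted data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
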