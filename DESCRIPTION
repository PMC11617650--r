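Package: reemtools
Title: Engineered Enviromic Markers and Reaction-Norm Ensemble Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An enviromics toolkit for genotype-by-environment (G x E)
    analysis in plant breeding. Engineers synthetic enviromic markers from
    high-dimensional environmental covariates with regression-tree ensembles,
    fits ensemble random-regression reaction-norm mixed models with pedigree
    kinship (REML), delineates breeding zones from genetic correlations among
    grid bins, derives per-bin genotype and parental-line recommendations with
    geographic representativeness, and validates predictions with
    leave-one-trial-out and leave-region-out cross-validation plus ordinary
    kriging of predictive-ability surfaces. Includes a synthetic-data
    generator with the exact statistical structure the model assumes, so the
    whole pipeline is testable without proprietary trial or satellite data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rpart,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
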