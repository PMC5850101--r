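Package: qsarRM
Title: Replacement-Method Linear QSAR Modelling with Balanced Splitting,
    Validation and Applicability Domain Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds multivariable linear regression QSAR
    (quantitative structure-activity relationship) models from large
    precomputed molecular descriptor pools. Implements descriptor-pool
    prefiltering (constant, near-constant, missing-value and collinear
    column removal), balanced train/validation/test splitting via k-means
    clustering, the replacement-method descriptor subset search that
    minimises the regression standard deviation, an internal and external
    validation battery (leave-one-out and leave-n%-out cross-validation,
    Y-randomization, Golbraikh-Tropsha criteria, outlier counting),
    applicability-domain assessment by the leverage and standardization
    approaches (Williams plot table), and conversion of regression
    predictions into active/inactive classes scored with Cooper statistics
    and the Matthews correlation coefficient. A synthetic-data generator
    emulates kinase-inhibitor descriptor matrices with planted linear
    signal so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'io.R'
    'synthetic.R'
    'prefilter.R'
    'mlr.R'
    'bsm.R'
    'rm-search.R'
    'validation.R'
    'ad.R'
    'classification.R'
    'pipeline.R'
    'qsarRM-package.R'
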