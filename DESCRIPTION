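Package: mwaskit
Title: Metabolome-Wide Association Analysis of LC-MS Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case-control metabolome-wide association analysis for untargeted
    LC-MS feature tables: presence filtering, feature-wise two-group testing on
    raw and log2 scales with Benjamini-Hochberg false discovery rate control,
    Pearson-correlation ion clustering of discriminatory features, multi-adduct
    metabolite annotation against a mass database within a ppm tolerance,
    OPLS-DA panel selection with linear discriminant classification and
    cross-validation, plus a synthetic case-control cohort generator with
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    mclust
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mixOmics,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
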