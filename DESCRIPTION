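Package: pfasweb
Title: PFAS Transfer Through an Aquatic-Terrestrial Food Web
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Contaminant biomonitoring toolkit for per- and
    polyfluoroalkyl substance (PFAS) movement through linked
    aquatic-terrestrial food webs. Handles left-censored concentration
    data (detection-frequency screening, robust regression-on-order-
    statistics imputation), builds per-sample congener profiles,
    estimates bootstrap sample-size-balanced bioaccumulation and
    biomagnification factors across compartment pairs, and provides a
    diet-tracer multivariate suite (arcsine-square-root transform, PCA,
    Pillai-trace MANOVA, Tukey-Kramer post hoc tests, multiple factor
    analysis). Ships published compartment summaries as fixtures and
    synthetic generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
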