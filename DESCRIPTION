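Package: pbmetab
Title: Plackett-Burman Robustness Screening for Untargeted LC-MS
    Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing metabolite extraction protocols and
    robustness-testing the chosen protocol with Plackett-Burman screening
    designs. Provides construction, validation and decoding of
    Plackett-Burman design matrices with dummy factors and centre points;
    noise filtering and cross-sample alignment of LC-MS peak lists under
    ppm and retention-time tolerances; adduct-group annotation; the
    feature-quality cascade (blank exclusion, all-replicate presence,
    coefficient-of-variation classification); extraction-method comparison
    summaries with exclusive UpSet-style intersection counts; hierarchical
    linear modelling of factor effects on log metabolite abundances with a
    deterministic penalized-maximum fit and a Gibbs sampler; QC injection
    drift checks; and a seeded synthetic-data generator with recorded
    ground truth so the whole pipeline is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
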