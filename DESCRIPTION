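Package: lagerscale
Title: Consumer-Weighted Sensory Evaluation Scales for Pale Lager
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds consumer-oriented sensory evaluation scales for pale
    lager from questionnaire data. Derives subjective attribute weights
    from Likert rating means via a ratings-driven analytic hierarchy
    process (min-max mapping onto the Saaty 1-9 scale), objective weights
    via the entropy weight method, fuses the two by a fixed subjective:
    objective ratio, and aggregates drinking-frequency cohorts with
    frequency-weighted population coefficients. A three-step
    standardization (attribute merging, exclusion, top-k selection, local
    and global normalization, integerization) turns the comprehensive
    weights into a practical scorecard, and rank-concordance statistics
    (Kendall's tau-b, Spearman's rho) validate scales against consumer
    hedonic rankings. Includes a synthetic survey and tasting-session
    generator plus scale-reliability diagnostics (Cronbach's alpha, KMO,
    Bartlett's sphericity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
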