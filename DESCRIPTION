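Package: tilcea
Title: Cost-Utility Modelling of Tumor-Infiltrating Lymphocyte Therapy
    Versus Ipilimumab in Advanced Melanoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-state (progression-free, progressive disease, death)
    cohort cost-utility model for second-line treatment of unresectable
    stage IIIC-IV melanoma, comparing adoptive cell therapy with
    tumor-infiltrating lymphocytes against ipilimumab. Provides parametric
    survival fitting and extrapolation (log-logistic and alternatives) from
    either summary survival points or right-censored individual-patient
    data, a partitioned-survival cohort trace on a 3-month cycle with
    country-specific discounting, accumulation of life years, QALYs and
    itemised costs, incremental cost-effectiveness reporting with dominance
    classification, deterministic (tornado) and probabilistic sensitivity
    analyses with cost-effectiveness acceptability curves, and a seeded
    generator of synthetic individual-patient survival and EQ-5D utility
    data for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    flexsurv,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
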