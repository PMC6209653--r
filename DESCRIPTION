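Package: genemeta
Title: Case-Control SNP Association Meta-Analysis
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for genetic-association meta-analysis from
    per-study genotype counts: 2x2 exposure tables under allele, dominant and
    recessive genetic models; per-study odds ratios with Woolf standard
    errors and continuity correction; pooled odds ratios by Mantel-Haenszel
    fixed effects (Robins-Breslow-Greenland variance) and DerSimonian-Laird
    random effects; Cochran's Q and I-squared heterogeneity with a
    heterogeneity-driven choice between the two estimators; two-tier
    significance classification of variants for genetic-screening
    prioritisation; ethnicity and country subgroup analyses; counts-weighted
    allele-frequency summaries; leave-one-out sensitivity analysis; funnel
    data export and Egger regression for publication-bias assessment; and a
    synthetic multi-study case-control genotype generator with known ground
    truth for calibration and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
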