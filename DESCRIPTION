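Package: herbimpact
Title: Herbicide Mixture Toxicity and Impacts on Marine Primary Productivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative toolkit for assessing the impact of agricultural
    herbicide residues on coastal phytoplankton primary productivity.
    Fits sigmoid (logistic and Weibull) concentration-response curves for
    individual herbicides and inverts them for effect concentrations (ECx);
    normalizes multi-herbicide residue mixtures to equi-effective atrazine
    concentrations (toxic equivalents, TEQ) under the concentration-addition
    model; maps station-level residues to community primary-productivity
    inhibition through an anchor-calibrated community curve with regional
    summaries, exceedance fractions and chronological trend tests; estimates
    phytoplankton intrinsic growth and micro-zooplankton grazing rates from
    dilution experiments; and scores gridded agricultural herbicide risk
    via PEC/PNEC risk quotients with a four-class risk-point scale.
    Includes seeded synthetic-data generators emulating survey, plate,
    dilution and grid inputs so the full analysis chain is testable.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
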