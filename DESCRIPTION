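Package: socialscope
Title: Single-Neuron and Ensemble Analysis of Social Threat Encoding in
    Miniscope Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing microendoscopic calcium imaging recorded
    during social defeat, approach-avoidance, context re-exposure and
    resident-intruder aggression assays. Covers movie preprocessing
    (background division, translation registration, ROI trace extraction,
    delta-F-over-F, cross-session ROI tracking), conversion of behavioural
    ethograms and chamber-occupancy tracks into frame-wise predicates,
    auROC-based responder classification against a shuffled-label null,
    peri-event statistics with exact Wilcoxon signed-rank tests, linear
    discriminant ensemble analysis (cluster distances, session-remodeling
    Kolmogorov-Smirnov tests, cross-validated session decoding), and
    responder-overlap statistics (product-chance estimates, Fisher's exact
    test, Venn counts). A seeded synthetic-experiment generator plants known
    responder classes, GCaMP6s-like kinetics and optional across-session
    tuning remodeling so that every stage can be validated against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    MASS,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
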