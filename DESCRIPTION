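Package: nfemg
Title: Quantitative Intramuscular EMG, Near-Fibre Stability Metrics and
    Ensemble Enrichment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of decomposed intramuscular
    electromyography (iEMG). Computes motor unit potential (MUP) features
    (duration, area, turns, mean inter-discharge interval), near-fibre (NF)
    metrics of neuromuscular-junction transmission stability (jiggle,
    segment jitter, NF count) via a second-order low-pass differentiator,
    and applies train-level quality control. Includes a statistical layer
    fitting gamma and inverse-Gaussian generalized linear models with
    subject clustering, BIC-based link selection and Holm-adjusted
    contrasts; a Monte-Carlo ensemble wrapper around preranked gene set
    enrichment with consensus leading-edge selection; force-trace metrics
    (MVC, time to 63% of MVC, specific force); and a motor-unit simulator
    that generates MUP trains with controllable latency jitter, impulse
    blocking and amplitude variability so every stage can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    sandwich,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
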