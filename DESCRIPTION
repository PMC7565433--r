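Package: iowattn
Title: Attentional Phenotyping from Infant Cued-Attention Eye Tracking
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable analysis pipeline for infant spatial-cueing (IOWA task)
    eye-tracking studies. Classifies raw 300 Hz gaze streams into fixations and
    saccades with a velocity-threshold (I-VT) filter, scores cued-orienting
    trials into saccadic reaction times and accuracies, derives six
    baseline-normalized attention scores per infant, identifies attentional
    phenotypes by latent profile analysis (diagonal-covariance Gaussian
    mixtures fit by EM with missing-data support), compares random-intercept
    growth-curve models of score development by likelihood-ratio tests, and
    computes visual short-term-memory looking measures (total looking, switch
    count) with the associated nonparametric, bootstrap and repeated-measures
    tests. A synthetic-data generator emulating phenotype score structure,
    gaze noise and dropout makes every stage testable without infant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    nlme,
    withr
Config/testthat/edition: 3
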