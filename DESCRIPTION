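Package: cervelast
Title: Tactile-Ultrasound Cervical Elastography: Simulation, Echo Tracking
    and Preterm-Birth Risk Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates pulse-echo tactile-ultrasound examinations of a
    compressing pregnant cervix, recovers the internal-surface echo depth per
    frame by complex Gaussian wavelet envelope detection and time-of-flight
    ranging, fits the cervical stress-to-strain ratio (elasticity, kPa/mm)
    and zero-pressure cervical length from the pressure-depth trajectory, and
    reproduces cohort-level diagnostic statistics for spontaneous preterm
    birth prediction: pooled t-tests from summary statistics, empirical ROC
    area with DeLong confidence intervals, and sensitivity/specificity with
    exact binomial confidence intervals at an elasticity cutoff.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
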