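Package: dyadsync
Title: Dyadic Biobehavioral Synchrony from Interbeat Intervals and
    Behavioral Micro-Codes
Version: 0.1.0
Authors@R:
    person("Dyadsync", "Maintainers", email = "maintainers@dyadsync.org",
           role = c("aut", "cre"))
Description: Estimates second-by-second respiratory sinus arrhythmia (RSA)
    from interbeat-interval series via cubic-spline resampling and
    multitaper short-time spectral band power, computes dyadic physiological
    and positive-affect synchrony (lag-0 cross-correlation of
    first-differenced RSA, Fisher transformed; shared positive affect from
    per-second behavior codes), derives parenting indicators and coder
    reliability (time-unit kappa), and fits moderation models of child
    depressive symptoms probed with simple slopes and Johnson-Neyman regions
    of significance. Includes a coupled-dyad simulator so the whole pipeline
    is testable without participant data, and a config-driven runner with
    exclusion accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
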