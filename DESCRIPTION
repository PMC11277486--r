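Package: phormiadev
Title: Thermal Development and Degree-Day Models for Phormia regina
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modeling constant-temperature development of the
    black blow fly Phormia regina (Diptera: Calliphoridae) from destructive
    cohort-sampling stage counts. Fits Gaussian-family stage-transition
    curves (Gaussian, plateau-modified Gaussian, cumulative and reversed
    cumulative Gaussian) to proportion-in-stage time series, estimates 50%
    stage-transition times by probit and cumulative-Gaussian regression,
    and builds validated linear degree-day models (developmental minimum,
    accumulated degree-days per stage and transition, valid temperature
    range) through iterative runs-test pruning and zero-slope validation of
    degree-day accumulations. Includes a synthetic cohort generator that
    emulates the multi-temperature destructive sampling design, and the
    published reference tables for P. regina used to check the analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    readxl,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
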