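Package: rewardmountain
Title: Reward-Mountain Modelling of Intracranial Self-Stimulation Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fitting and probing the reward-mountain model of
    brain stimulation reward: the matching-law surface relating time
    allocation to pulse frequency and price, extended with the
    subjective-price and frequency-following transforms and a
    dual-integrator variant governed by strength-duration (rheobase and
    chronaxie) laws. Includes computation of time allocation from
    time-stamped lever-event streams, a pseudo-sweep survey-design
    generator with a synthetic operant-session simulator, joint
    nonlinear least-squares fitting across train durations, and
    case-resampling bootstrap inference on the mountain's location
    parameters including detection of train-duration-induced shifts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    tibble,
    dplyr,
    readr,
    rlang,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
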