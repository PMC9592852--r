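Package: reachvigor
Title: Simulation and Analysis of Threat-Conditioned Reaching Vigor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for studying how Pavlovian threat learning
    invigorates goal-directed reaching. Generates constrained trial schedules
    for baseline, conditioning and test phases; simulates 100 Hz mouse-cursor
    reaches with a minimum-jerk velocity profile and a configurable CS+
    invigoration effect, and event-related skin-conductance traces with
    larger phasic responses to CS+ than CS-; scores trajectories (peak
    velocity, acceleration, deceleration, reaction time, endpoint accuracy,
    anomaly screening) and skin conductance (trough-to-peak amplitudes under
    onset-window, rise-time and minimum-amplitude validity rules); and runs
    the within-subject statistical suite (repeated-measures ANOVA with
    Greenhouse-Geisser correction, Helmert contrasts, paired t-tests, partial
    eta-squared and Cohen's d with noncentral confidence intervals,
    within-subject descriptive intervals, and outlier-screened Pearson
    correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
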