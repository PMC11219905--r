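Package: faidsim
Title: Fully Automatic Insulin Delivery: Closed-Loop Simulation, Meal
    Detection and Deep-RL Bolus Dosing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale in-silico test bench for fully automatic insulin
    delivery (FAID) in type 1 diabetes. Provides a Bergman minimal-model
    virtual patient with circadian insulin-sensitivity variability, meal
    scenarios and CGM sensing; a proportional-derivative controller with
    insulin feedback and a sliding-mode insulin-on-board safety layer; an
    unscented-Kalman-filter detector of unannounced meals driven by a
    disturbance state; a multi deep-Q-network bolus calculator trained by
    experience replay; a guideline standard bolus calculator baseline with
    carbohydrate misestimation; consensus CGM outcome metrics (time in
    range, GMI, GRI) and paired nonparametric comparison of delivery arms.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
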