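Package: cyclopred
Title: Predicting Cycloplegic Spherical Refraction from Non-Cycloplegic Biometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives crystalline-lens optical features from routine
    non-cycloplegic measurements (autorefraction, keratometry, optical
    biometry) via three SRK/T-based formulations, screens them with
    L1-penalised regression, and fits gradient-boosted regression models
    for cycloplegic spherical refraction, with a full evaluation battery
    (error metrics, paired t-tests, Bland-Altman limits of agreement,
    age-subgroup and baseline-model comparisons). Also provides the
    accommodation-optics analyses that motivate the lens features:
    quadratic curvature-accommodation fitting, thick-lens power from
    anterior-segment geometry, and image-principal-plane offset. A seeded
    synthetic-cohort generator emulates the paediatric study population.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    glmnet,
    xgboost,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
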