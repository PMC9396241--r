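Package: tepredict
Title: Predicting Treat-and-Extend Outcomes in Neovascular AMD from
    Quantitative OCT Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for predicting visual outcomes and
    retreatment intervals of a treat-and-extend (T&E) anti-VEGF regimen in
    neovascular age-related macular degeneration from early quantitative
    optical coherence tomography (OCT) biomarkers. Provides a seeded
    synthetic cohort generator emulating the data structure of a T&E trial
    arm (en-face biomarker thickness maps, fluid kinetics, latent-class
    BCVA trajectories, interval dynamics), ETDRS-grid zonal feature
    extraction, a T&E regimen state machine with outcome labelling, a
    latent class mixed model fitted by EM for trajectory clustering, and
    random-forest outcome prediction evaluated with stratified
    cross-validation, ROC/AUC with bootstrap confidence intervals and
    permutation feature importance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    randomForest,
    generics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    lme4,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
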