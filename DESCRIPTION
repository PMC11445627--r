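Package: arrestwatch
Title: Hourly Cardiac-Arrest Risk Alarms from ICU Vital-Sign Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An early-warning pipeline that turns irregular intensive-care
    vital-sign streams into hourly cardiac-arrest risk alarms over a 24-hour
    horizon. Irregular observations are bucketed to an hourly grid, imputed by
    last-observation carried backward then forward, range-filtered and min-max
    normalized; Modified Early Warning Score channels are derived per vital;
    12-hour lookback windows yield time-step, multiresolution statistical and
    Gini-dispersion features; an ensemble screen (recursive feature elimination
    plus a shadow-feature relevance test) selects candidates by majority vote;
    a cost-sensitive attentive tabular classifier with per-step feature masks
    produces interpretable probabilities; and a pseudo-real-time
    leave-one-patient-out harness scores alarms with event recall and false
    alarm rate. A synthetic ICU generator makes every stage testable without
    credentialed data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    withr,
    zoo,
    xgboost,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071,
    yaml,
    optparse,
    jsonlite
Config/testthat/edition: 3
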