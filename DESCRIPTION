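Package: helmetkin
Title: Head Kinematics Estimation from Helmet-Embedded Accelerometers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to estimate head linear and rotational acceleration time
    histories during helmeted head impacts from twelve single-axis
    accelerometers mounted tangentially on the helmet shell. Provides Latin
    Hypercube design of impact scenarios over orientation and impact-speed
    parameters with optional reshaped marginals, a lumped-parameter rigid-body
    surrogate simulator of the helmeted-head ground impact (penalty contact,
    distributed viscoelastic liner, regularized Coulomb friction), phaseless
    SAE J211 channel-frequency-class filtering, bidirectional LSTM
    sequence-to-sequence estimators trained with RMSprop and
    back-propagation through time, head injury metrics (HIC, RIC) with a
    verified sliding-window maximization, and R-squared based assessment of
    estimator performance including an exclusion rule for extreme rotational
    accelerations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    lhs,
    readr,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    signal,
    optparse
Config/testthat/edition: 3
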