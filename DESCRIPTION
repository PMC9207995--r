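Package: netbridge
Title: Network-Based Regression Linking Behavioural Trait Networks and
    Functional Connectomes
Version: 0.1.0
Authors@R:
    person("netbridge", "developers", email = "netbridge@example.org",
           role = c("aut", "cre"))
Description: Derives unique-variance behavioural regressors by
    residualizing correlated trait scores, identifies their functional
    connectome correlates with connectome-based predictive modelling
    (CPM) under nested cross-validated parameter tuning, consensus edge
    selection and permutation inference, and estimates joint
    behaviour-brain networks with unregularized Gaussian graphical
    models selected by the extended Bayesian information criterion and
    with constraint-based Bayesian network structure learning
    (Grow-Shrink, IAMB variants, MMPC) under multiple conditional
    independence tests. Includes seeded synthetic-data generators that
    emulate the statistical structure the pipeline assumes, connectome
    construction from ROI time series (Pearson, shrinkage partial
    correlation, tangent-space embedding), edge-wise confound
    regression, QC subject filters, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
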