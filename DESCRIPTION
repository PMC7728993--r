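Package: dcmWC
Title: Dynamic Causal Modeling for fMRI with Wilson-Cowan Neuronal Equations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generative modeling and variational Bayesian inversion of
    dynamic causal models (DCM) for fMRI in which the neuronal state
    equation is either the classical bilinear form or a Wilson-Cowan
    sigmoid relaxation, in single- and two-state (excitatory/inhibitory)
    variants. Includes the balloon/windkessel hemodynamic forward model,
    fixed-step RK4 integration on a microtime grid, variational Bayes
    under the Laplace assumption with free-energy model evidence,
    fixed- and random-effects Bayesian model selection with protected
    exceedance probabilities, family-level inference, Bayesian model
    averaging, exhaustive model-space enumeration, and a synthetic-data
    harness for SNR sweeps, explained variance and connection-detection
    ROC/AUC benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, Rcpp, jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), pROC, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
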