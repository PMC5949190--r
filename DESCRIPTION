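Package: mklpso
Title: Multiple Kernel Learning SVM Tuned by Particle Swarm Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Binary classification of pulmonary-nodule candidate regions
    (ROIs) with a support vector machine whose kernel is a convex mixture
    of a polynomial and a radial basis kernel. The hyperparameters
    (regularization C, RBF width g, mixture weight m) are tuned by
    particle swarm optimization under six inertia-weight schedules with
    cross-validated accuracy as the fitness, alongside a grid-search
    baseline, convergence diagnostics for fitness traces (normalized
    Euclidean error norm, convergence generation, Tukey boxplot
    statistics), and generators for imbalanced synthetic feature tables
    with controllable separability and nonlinear class structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
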