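Package: spinedyn
Title: Spine-Size Distributions and Synaptic Weight Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the right-skewed, lognormal-like distribution
    of dendritic spine head sizes and for modelling how it arises. Provides
    integral-normalised histogram fitting of the lognormal density (with
    Gaussian fits in log-space, skewness and log-sd diagnostics, and AIC
    comparison against gamma and Weibull), a nonparametric comparison battery
    for per-cell fit metrics across hemispheres, dentate layers, cell ages and
    genotype groups, a population simulator of synaptic weight dynamics in
    leaky integrate-and-fire neurons combining intrinsic Kesten-type
    multiplicative/additive noise with exponential-window STDP and uniform
    heterosynaptic scaling, sequential rejection-ABC inference of the six
    plasticity parameters from lognormal summary features, and seeded
    synthetic-data generators emulating adult-born granule cell and CA1
    pyramidal cell spine datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    fitdistrplus,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
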