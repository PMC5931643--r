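Package: SpikeNetGLM
Title: Active Inference of Directed Functional Connectivity from Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers sparse directed functional-connectivity networks from
    binned spike-count time series and external stimulus indicators with a
    Poisson generalized linear model using a softplus-kappa nonlinearity.
    Edges are selected by an elastic-forward search that minimizes BIC under
    a Wald-test p-value ceiling, evaluated over bootstrap subsamples.  An
    active-learning module scores every stimulus by the deviance-weighted
    expected rate change of candidate edges and emits the stimulus
    distribution for the next acquisition batch.  Includes small-world
    ground-truth network generators, Poisson and leaky integrate-and-fire
    spiking simulators, Hartley stimulus encoding, edge-recovery metrics,
    long-range rate forecasting, and a motif/clique/degree small-world
    analysis suite.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
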