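Package: dyadmir
Title: Frequency-Domain Causal Influence Between Interacting Brains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Directed connectivity inference for dyadic (two-person)
    physiological time series such as fNIRS hyperscanning recordings.
    Fits linear state-space models to paired multichannel epochs,
    decomposes the spectral interdependence (the frequency-domain
    mutual information rate) into two directed terms and an
    instantaneous term, forms a signed causal-intensity spectrum and
    its band integral, assesses per-frequency significance with
    phase-randomization surrogates, and calibrates the direction
    decision against short-distance nuisance channels. Includes a
    synthetic dyad simulator with known ground-truth direction for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
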