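Package: movesyndromes
Title: Classification of Animal Movement Syndromes from Trajectory Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes five trajectory-level movement metrics (turn angle
    correlation, residence time, time-to-return, monthly kernel home-range
    overlap, and maximum net squared displacement) on regularized animal
    relocation data, simulates idealized movers for four movement syndromes
    (central-place foraging, territoriality, nomadism, migration), and
    classifies individuals by principal components analysis with broken-stick
    component retention, Ward hierarchical clustering, and multiscale
    bootstrap cluster support, labeling clusters by co-clustered simulated
    reference movers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    ape,
    geosphere,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
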