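Package: causalspace
Title: Causality Networks in Sensor and Source Space
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and comparison of directed causality networks estimated
    in the sensor space (multichannel recordings) and in the source space
    obtained through a standardized weighted-Laplacian minimum-norm inverse
    (sLORETA-style). Provides generators for random, small-world and scale-free
    coupling networks, simulators for coupled Henon maps, coupled Mackey-Glass
    delay systems and first-order vector autoregressions, a synthetic spherical
    head model with the standardized inverse and ROI averaging, the restricted
    conditional Granger causality index (RCGCI) with modified backward-in-time
    selection, the partial mutual information from mixed embedding (PMIME) with
    k-nearest-neighbour information estimates, five graph metrics of binarized
    causality networks, and AUROC-based discrimination of network types and of
    epileptiform-discharge epochs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, igraph, Matrix, Rcpp, signal, jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), deSolve, withr, optparse, knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
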