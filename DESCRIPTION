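Package: bgoafs
Title: Binary Grasshopper Optimization with Time-Varying Transfer
    Functions for Wrapper Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Wrapper feature selection for tabular classification data
    using a binary grasshopper optimization algorithm.  Continuous swarm
    dynamics (social force, shrinking comfort coefficient, elitist target
    attraction) are mapped to bit masks through transfer functions: the
    classic S-shaped and V-shaped families, a time-varying sine transfer,
    and a time-varying V-shaped transfer with additive Gaussian mutation
    whose steepness and mutation scale shrink linearly over iterations.
    Candidate feature subsets are scored by the hold-out error of a
    deterministic k-nearest-neighbour classifier combined with a
    subset-size penalty.  Includes a synthetic-data generator with ground
    truth, an exhaustive-search oracle for small dimensions, run-level
    statistics, confusion-matrix indices, CSV/JSON reporting, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    class,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
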