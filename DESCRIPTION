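Package: fcploidy
Title: Flow Cytometric Genome Size Evaluation and Cytotype Delimitation
    in Mixed-Ploidy Plant Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring cytotype structure from flow cytometric (FCM)
    measurements of plant genome size. Evaluates raw fluorescence event data
    co-stained with an internal standard (histogramming, peak detection,
    per-peak mean and coefficient of variation, genome size in picograms,
    quality filtering), fits one-dimensional Gaussian finite mixtures to
    genome sizes by expectation-maximisation, compares candidate component
    numbers by a redundancy criterion, delimits genome-size groups anchored by
    chromosome counts, assigns individuals to groups or leaves them
    unassigned, and summarises cytotype composition and habitat association at
    the population level. Includes a synthetic-data generator emulating
    co-stained FCM analyses of a mixed-ploidy polyploid complex for testing
    and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
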