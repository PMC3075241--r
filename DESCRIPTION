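Package: ethotracer
Title: Rule-Based Lifetime Ethogram Analysis for Caged Insect 3D Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating, classifying and summarizing the lifetime
    behavior of individually caged flies recorded by a stereo-vision monitor.
    Provides a six-state semi-Markov trajectory simulator with diurnal and
    age modulation, an idealized pinhole stereo rig (blob rendering, centroid
    detection, triangulation), a deterministic distance-threshold classifier
    for six behaviors (resting, micro-movement, walking, flying, feeding,
    drinking) plus a mortality rule, lifetime descriptive analytics
    (hourly activity matrices, circadian and age profiles, cage-top
    occupancy, rest-bout tables, event-history charts, survival curves), and
    age-group behavioral clustering with Euclidean and optimal-matching
    dissimilarities, dendrograms, bootstrap support and Newick export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    ape,
    survival,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'classify.R'
    'cluster.R'
    'simulate.R'
    'cohort.R'
    'ethotracer-package.R'
    'io.R'
    'stereo.R'
    'summarize.R'
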