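Package: camassoc
Title: Species Association and Diel Activity Analysis for Camera-Trap Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring interspecific spatial association networks from
    camera-trap detection records. Collapses raw captures into independent
    detection events by a 30-minute rule, screens species by relative abundance,
    computes Levins and Shannon distributional breadth and Pianka spatial
    co-occurrence, tests community-wide association with Schluter's variance
    ratio, quantifies pairwise association with the Phi coefficient and
    Yates-corrected chi-square, measures asymmetric predictability with the
    Goodman-Kruskal lambda, estimates diel activity overlap between species with
    circular (von Mises) kernel densities and smoothed-bootstrap confidence
    intervals, and assembles the resulting signed, partly directed association
    network. Includes a synthetic camera-trap community generator with
    controllable occupancy, pairwise association, detection intensity and
    activity rhythms for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
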