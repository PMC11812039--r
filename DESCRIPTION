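Package: branchscale
Title: Branch-Thickness Scaling and Fractal Dimension of Trees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the scaling of branch thickness in trees,
    whether drawn, carved, painted or simulated. Generates random
    self-similar trees in which the radius scaling exponent alpha is
    preserved exactly at every ramification (r_a^alpha + r_b^alpha =
    r_c^alpha), reads branch-diameter annotations from SVG line overlays
    and plain CSV lists, estimates alpha by maximum likelihood on
    logarithmically binned diameters with bootstrap confidence intervals
    and tail-distribution diagnostics, and measures the box-counting
    fractal dimension of rasterised trees by dyadic-grid regression.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
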