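Package: markerGP
Title: Genetic-Programming Forecasts of Cancer Stem-Cell Marker Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Symbolic regression by genetic programming for flow-cytometry
    time courses of cancer stem-cell marker expression. Evolves expression
    trees of time over a fixed function set to fit per-timepoint replicate
    means of marker-positive cell percentages, validates each model blind at
    a held-out timepoint via the coefficient of determination, and forecasts
    expression beyond the observation window. Includes a synthetic-data
    generator emulating a nine-system treated-versus-control study design,
    an exact small-sample Mann-Whitney rank test, and a small command-line
    interface for simulate/fit/report runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rlang,
    tibble,
    withr,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
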