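Package: gpoincare
Title: Generalized Poincare Plot Analysis of RR-Interval Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for generalized Poincare plot analysis of heart-rate
    tachograms. Builds summed-window scatter plots of j preceding versus k
    following RR intervals, tabulates the Pearson correlation matrix r(j,k)
    over a grid of orders, quantifies its asymmetry with a normalized
    asymmetry index corrected by reshuffled surrogates, detects and clusters
    local correlation maxima across subjects, and generates synthetic
    validation tachograms with a planted correlation maximum at a chosen
    order. Includes SD1/SD2 descriptors, plotting, CSV input/output and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
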