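Package: infoens
Title: Significance Testing and Comparison of Ensembles of Information Sources
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analyzing ensembles of information sources, such as the
    mutual information carried by every pairwise connection in a recorded
    neural population or by each neuron about a stimulus. Each source's
    information value is tested against a surrogate null distribution built by
    permuting one variable, yielding Monte Carlo p-values with an explicit
    floor. Whole ensembles are tested against their pooled surrogate null with
    a two-sample Kolmogorov-Smirnov test (sensitive to both excess and
    suppressed information), summarized by p-value-weighted mean, standard
    error, and standard deviation, and compared to one another with a
    permutation test on the difference of weighted means. A simple two-variable
    binary generative model with tunable interaction strength and noise level
    supports calibration studies and power analyses, and ensembles can be read
    from and written to plain tab-separated files for use with externally
    computed information values.
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
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
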