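Package: fpgcm
Title: Growth Curve Models with Fractional Polynomials for Incomplete
    Time-Course Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits per-gene growth curve (linear mixed) models in which time
    enters through fractional polynomial transformations drawn from the fixed
    power set {-2, -1, -0.5, 0, 0.5, 1, 2, 3}.  Restricted maximum likelihood
    estimation handles unbalanced designs arising from missing microarray
    chips, AIC compares the fixed grid of candidate transformations per gene,
    and Benjamini-Hochberg false discovery rate control screens thousands of
    genes for significant time-course patterns.  Includes a synthetic
    time-course generator, a power-versus-missingness simulation engine,
    trajectory clustering of significant genes, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
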