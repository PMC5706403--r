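Package: distnorm
Title: Distribution-Based Normalization for Cross-Platform Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Normalizes expression matrices measured on different platforms by
    fitting parametric probability density functions (polynomial, Fourier
    series, Gaussian, or user-defined) to each source's pooled intensity
    distribution and mapping every value to the target value of equal
    cumulative probability. Includes the classical comparator normalizers
    (z-score, average-difference scaling, quantile normalization), evaluation
    statistics (binned Kullback-Leibler divergence, six-number summaries,
    MA-plot statistics), and a synthetic multi-platform data generator with
    platform-specific location, scale, and skew effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    limma,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
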