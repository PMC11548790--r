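Package: sparsemet
Title: Sparse Testing Designs and Bayesian GBLUP for Multi-Environment Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sparse testing in plant breeding multi-environment trials:
    marker quality control and VanRaden genomic relationship matrices, incomplete
    block and constrained-random allocation of lines to environments, Bayesian
    GBLUP with genotype-by-environment interaction under six environment-covariance
    constructions (including a first-stage unstructured covariance estimate), and
    genotype-selection quality metrics (Pearson correlation, normalised RMSE,
    top-fraction percentage matching, relative efficiency) evaluated by
    cross-validation in which every line is observed in at least one environment.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
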