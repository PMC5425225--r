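Package: avalanchr
Title: Neuronal Avalanche and Criticality Analysis for Population Spike Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for assessing criticality in neural population
    recordings: avalanche detection from binned network activity with a median
    threshold, maximum-likelihood fitting of doubly truncated discrete power
    laws with iterative support selection, surrogate-based Kolmogorov-Smirnov
    goodness-of-fit testing, bootstrap exponent uncertainty, the crackling-noise
    scaling relation between mean avalanche size and duration, interspike-interval
    irregularity statistics, and stimulus-dependent pairwise correlation
    structure. Includes a probabilistic branching-network simulator with a
    calcium-imaging forward model so the full pipeline is testable end to end
    on synthetic data, plus preprocessing from fluorescence traces (sliding
    dF/F, sparse non-negative deconvolution, population-SD thresholding).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    e1071
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
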