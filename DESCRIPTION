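Package: clockvar
Title: Transcriptional Variability Analysis of the Zebrafish Segmentation Clock
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes cell-to-cell transcriptional variability of the paired
    zebrafish segmentation clock genes her1 and her7 into correlated and
    uncorrelated components over phase-grouped (single-cell-wide) slices of the
    presomitic mesoderm, compares genotypes by bootstrap resampling of the area
    under the variability-versus-mean curve with a paired t-test, and simulates
    a delayed stochastic oscillator with correlated transcriptional bursting,
    Hill repression of burst size by the Her1-Her7 heterodimer, and Erlang
    delay chains. Includes a synthetic single-molecule FISH data generator
    (Poisson-lognormal mixture with kinematic-wave spatial profiles and
    lognormal cell volumes) with closed-form ground truth, so the whole
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    pracma,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
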