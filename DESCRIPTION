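Package: thetanav
Title: Intermittent Theta Dynamics During Real-World and Imagined Navigation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for intermittent medial-temporal-lobe theta
    oscillations recorded during real-world and imagined navigation along
    segmented walking routes. Provides Morse-wavelet time-frequency
    decomposition with individualized theta-band selection, interictal
    epileptiform discharge rejection, oscillatory-bout detection against a
    1/f background, dynamic-time-warping trial alignment, split-half
    temporal-consistency statistics with multilevel block permutation
    inference, and a cross-validated linear decoder that reconstructs
    relative position within route segments as a circular variable. A
    synthetic-session generator with known ground truth makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
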