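Package: loopstage
Title: Phase-Shifted Gene-Pair Loops for Staging Inflammation and Resolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects pairs of genes whose longitudinal expression profiles are
    phase-shifted by about a quarter period, so that plotting one against the
    other traces a loop through expression phase space. Time courses are
    discretised with symbolic aggregate approximation (SAX), shifted search
    patterns identify candidate pairs, a polar transformation about a
    minimum-radius-variance centre scores how faithfully the loop angle
    recapitulates time, and a k-nearest-neighbour classifier on the two-gene
    plane predicts the perturbation time or stage of withheld samples.
    Includes a synthetic longitudinal expression generator with planted
    looping pairs, leave-one-individual-out cross-validation, noise
    sensitivity analysis, and a random-pair null comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
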