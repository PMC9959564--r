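Package: circfold
Title: Secondary Structure and Folding Stability Prediction for Circular RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts secondary structures and folding free energies of
    circular RNAs (covalently closed, no 5'/3' ends) from sequence alone.
    Saturated helices are enumerated on the circle and the most stable ones
    partition the folding landscape into discrete structural ensembles via
    inclusion/exclusion signatures. For each ensemble the conditional
    partition function is computed over a two-linear-fragment decomposition
    of the circle and the minimum free energy structure is recovered by
    backtracking, under a nearest-neighbor Turner energy model. Users may
    force helices (HELIX i j k) or unpaired stretches (LOOP i k). An
    exhaustive small-N enumeration oracle is included for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: C++17
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
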