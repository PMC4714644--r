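Package: bowsvm
Title: Bag-of-Words fMRI Features and Semi-Supervised SVMs for Cochlear-Implant Outcome Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts post-cochlear-implant language outcome classes from
    pre-implant fMRI contrast t-maps. Implements bag-of-words featureization of
    thresholded 3-D contrast maps (Student-t threshold bins, 26-connected
    components harvested across a cohort into a region dictionary), supervised
    and semi-supervised (transductive) linear support vector machines with
    annealed label switching, recursive feature elimination, leave-one-out and
    nested leave-one-out evaluation, and classifier stability diagnostics.
    Ships a synthetic cohort generator with planted discriminative regions and
    the printed outcome-score table so the whole pipeline runs without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
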