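Package: thalatrack
Title: Connectivity-Based Thalamic Targets from Probabilistic Tractography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates connectivity-based neurosurgical targets (CBTs)
    in the thalamus from probabilistic streamline tractography. Provides a
    synthetic multi-subject, multi-scanner diffusion phantom with analytic
    fiber-bundle geometry, a Watson-model probabilistic tracker with ordered
    way-point filtering and waytotal normalization, percentile thresholding of
    connectivity maps, Dice-overlap and centre-of-gravity evaluation against
    atlas targets, a product-of-medians consensus rule for selecting the
    optimal connectivity threshold, and a decomposition of CBT reproducibility
    into inter-subject and inter-scanner components, including the
    cerebello-thalamic tract analysed in a slab around the AC-PC plane.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
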