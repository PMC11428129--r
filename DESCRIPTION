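Package: rpsb2pa
Title: Two-Photon Absorption Analysis for Retinal Chromophore Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Few-state sum-over-states construction of two-photon transition
    moments, rotational averaging of two-photon tensors for Hermitian and
    non-Hermitian response theories, conversion of microscopic two-photon
    transition strengths (atomic units) to macroscopic cross sections
    (Goeppert-Mayer units) with a Lorentzian lineshape, and a benchmarking
    layer that compares TD-DFT functionals against a coupled-cluster
    reference for retinal protonated Schiff base chromophore models. Ships
    a curated table of excitation energies, two-photon strengths and dipole
    properties for seven five-double-bond retinal models under five
    electronic-structure methods, plus a synthetic-manifold generator so
    every stage of the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
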