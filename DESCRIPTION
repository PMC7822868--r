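Package: surfid
Title: Information-Theoretic Limits on Surface Identification by Colour
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates how many surfaces in a scene can be distinguished, and
    identified again after an interval of changing illumination, from the
    colour signal alone. Converts hyperspectral radiance images to cone
    excitations and to CIECAM02, CIELAB and S-CIELAB coordinates, models
    observer internal noise referred to colour-discrimination thresholds,
    estimates differential entropy and mutual information of colour codes
    with a Kozachenko-Leonenko k-nearest-neighbour estimator, and fits the
    time course of the number of identifiable surfaces against the interval
    between acquisitions. A synthetic hyperspectral scene generator provides
    reflectance fields, daylight illuminants and spatially correlated
    illumination gain fields so the whole pipeline is testable without
    external scene data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    boot,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
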