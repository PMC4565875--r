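Package: isofine
Title: Isotopic Fine Structure Moments, Peak Counting, and Resolution Limits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes the isotopic fine structure of aggregated isotope
    variants of molecules built from C, H, N, O, P and S. Computes per-variant
    probabilities, center masses, variances and information-theory entropies
    with a polynomial generating-function convolution (no fine-structure
    enumeration required), decomposes total variance and entropy into
    within-variant and between-variant parts, counts fine peaks exactly as a
    bounded money-exchange problem, enumerates fine isotopologues with
    branch-and-bound pruning, and estimates resolution limits: overlap onset
    between adjacent aggregated variants, thermorelativistic mass uncertainty
    of isolated ions, divergence of the fine structure from normality, and
    ion-counting occupancy statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
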