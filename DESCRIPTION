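Package: ionct
Title: Image-Quality Modelling for Energy-Loss Ion Computed Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic model of image quality in energy-loss ion imaging for
    therapeutic beams (hydrogen, helium, lithium, boron, carbon) crossing a
    water cylinder. Implements Bethe-Bloch stopping power and depth-energy
    transport, Fermi-Eyges multiple Coulomb scattering moments and the
    tracker-constrained path envelope, Tschalar energy-loss straggling,
    propagation of energy noise to water-equivalent-thickness noise, the
    signal-to-noise-ratio/dose relation for a cylindrical phantom, and the
    modulation transfer function with pixel sampling. A seeded condensed-history
    electromagnetic Monte Carlo validates the analytic moments at desk scale.
    Published Monte Carlo nuclear parameters are shipped as fixtures.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
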