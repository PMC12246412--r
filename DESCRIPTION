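Package: chromorheo
Title: Single-Chromosome Optical-Tweezers Mechanics and Broadband Microrheology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for dual-trap optical-tweezers experiments on single
    mitotic chromosomes. Provides force-extension elasticity analysis (stretch
    modulus, power-law stiffening exponent, linear/non-linear response
    classification), single-step stretch-hold broadband microrheology (one-sided
    Fourier transform of non-uniformly sampled force and extension records,
    complex stiffness over about seven frequency decades, loss-tangent feature
    extraction), Burgers four-element viscoelastic model fitting, cohort-level
    statistics (Kruskal-Wallis with Dunn post-hoc comparisons, bootstrap
    confidence intervals), and an exact forward simulator of the dumbbell
    experiment that makes every stage testable without laboratory data.
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
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
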