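Package: beanbolus
Title: Particle Size, Digestion Kinetics and Texture Analysis of Masticated Bean Boluses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the oral breakdown and in vitro digestion of
    cooked legumes. Segments photographs of dispersed bolus particles on a
    calibrated plate into individual seed-coat and cotyledon fragments, fits
    the Rosin-Rammler cumulative particle-area distribution, models starch
    digestion time courses with a fractional conversion model and protein
    digestion with zero-order kinetics, computes rapidly digestible, slowly
    digestible and resistant starch fractions, derives pulsed electric field
    processing quantities and texture profile analysis parameters, and
    classifies participants into fast, slow and inconsistent chewers. A
    synthetic-data module generates plate images with ground truth, digestion
    curves, texture curves and chewer panels so the whole pipeline can be
    exercised and validated without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
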