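Package: ganmap
Title: GAN-Refined Simulation of Cryo-EM Density Maps from Atomic Models
Version: 0.1.0
Authors@R: person("ganmap", "developers", role = c("aut", "cre"),
    email = "ganmap@example.org")
Description: Simulates cryogenic electron microscopy (cryo-EM) density maps
    from atomic models with a Gaussian point-spread kernel, curates
    experimental maps into normalized training targets, trains a volumetric
    nested-U-Net (U-Net++) generative adversarial network that translates
    simulated maps into experimental-like maps, and scores map pairs with
    SSIM, plain and mean-centred cross-correlation, and the Pearson
    correlation coefficient. Includes MRC2014 and PDB/mmCIF readers, a
    deterministic 32-cubed tile/reassemble scheme, a synthetic fixture
    generator for offline desk-scale testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
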