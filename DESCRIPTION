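Package: dotinverse
Title: Machine-Learned Inverse Diffuse Optical Tomography in Slab Breast Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates continuous-wave diffuse optical tomography (DOT)
    measurements of a compressed-breast slab containing a spherical absorbing
    tumor, using analytic diffusion Green's functions with an image-source
    boundary treatment and a first-order perturbation model for the inclusion.
    Solves the inverse problem (tumor position, absorption coefficient and
    radius) with per-label gradient-boosted regression trees and refines each
    predicted label with a Koza-style genetic-programming symbolic-regression
    correction stage. Includes dataset generation, evaluation by RMSE and
    cosine similarity, reconstruction-slice rendering and a reproducible
    end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
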