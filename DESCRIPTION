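Package: tetraflex
Title: Deformation-Field Reconstruction of Flexible Macromolecules from Cryo-EM Particle Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative modelling of continuous conformational heterogeneity in
    single-particle cryo-EM. Jointly learns a canonical 3D density map, a neural
    flow generator defined over a tetrahedral finite-element mesh, and
    per-particle latent conformational coordinates from 2D particle images with
    known poses and CTFs. Density is transported by mass-conserving forward
    convection; motion is regularized by a local-rigidity penalty on the
    singular values of each element's affine deformation. Includes
    high-resolution half-map reconstruction under the frozen deformation model
    by full-batch L-BFGS, Fourier shell correlation validation, Cn
    symmetrization, a synthetic flexible-particle simulator with known ground
    truth, and minimal MRC/MRCS and STAR readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
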