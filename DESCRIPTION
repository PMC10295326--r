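Package: trabeculagen
Title: Micro-CT-Like Image Synthesis and Trabecular Bone Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying whether clinical-resolution (MDCT) images of
    vertebral trabecular bone can be translated into micro-CT-like images that
    support quantitative bone morphometry. Provides a synthetic vertebral
    phantom generator with known ground-truth microstructure, paired micro-CT
    and MDCT renderers, keypoint-based slice pairing via dynamic time warping,
    an unpaired image-to-image translation model (content/class encoders, an
    AdaIN-conditioned decoder and a patch discriminator trained with
    adversarial, reconstruction and feature-matching losses), morphometry of
    bone volume fraction, trabecular thickness and separation inside
    cylindrical volumes of interest (IsoData thresholding, local-thickness
    maps), similarity metrics (SSIM, Frechet distance on feature embeddings)
    and the accompanying statistical battery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    yaml,
    jsonlite,
    car
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
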