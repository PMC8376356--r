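Package: gmafm
Title: Reconstruction of 3D Oligomer Conformations from AFM Height Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs coarse-grained three-dimensional conformations of
    oligomeric proteins (hexameric AAA+ disaggregases such as ClpB) from single
    atomic-force-microscopy height images.  A structure is represented as a
    labeled 3D Gaussian mixture model (3 kernels per chain, 18 for a hexamer);
    pseudo-AFM images are rasterized from the kernels and compared to the
    target image with the structural similarity metric (SSIM).  Sampling is a
    two-step annealed Metropolis Monte-Carlo gated first on asymmetric harmonic
    kernel-overlap restraints interpolated between two reference conformations
    (with phantom-particle connectivity constraints), then on scaled SSIM.
    Includes reference-model preparation from atomic structures, a
    multi-trajectory two-phase selection and convergence protocol, density
    cross-correlation measures, PCA + DBSCAN conformational clustering, and a
    synthetic hexamer generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
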