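Package: eigenvault
Title: Extended Eigenshape Analysis of Cranial Vault Outlines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Outline-based geometric morphometrics of 2D cranial vault
    profiles. Reads and writes TPS landmark/outline files, splits vault
    outlines into homologous open segments anchored on craniometric
    landmarks (occiput, lambda, bregma, glabella), resamples segments to
    equidistant semi-landmarks, performs Generalized Procrustes
    superimposition to unit centroid size, converts outlines to
    Zahn-Roskies phi-functions (cumulative tangent angles), decomposes
    their covariance into eigenshapes, and runs stepwise Wilks'-lambda
    discriminant analysis with leave-one-out cross-validation and
    pairwise Mahalanobis distances. Includes a parametric generator of
    synthetic modified-cranium outlines (annular tall/oblique and
    two-bandage bregmatic-depression morphologies) so the full pipeline
    is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
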