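Package: riemalign
Title: Riemannian Transfer Learning for SPD Covariance Matrices Under the
    Log-Euclidean Metric
Version: 0.1.0
Authors@R:
    person("riemalign", "developers", email = "riemalign@example.org",
           role = c("aut", "cre"))
Description: Geometry, alignment and classification tools for symmetric
    positive definite (SPD) matrices, aimed at cross-session and
    cross-subject transfer in motor-imagery EEG decoding. Implements
    log-Euclidean metric (LEM) primitives with closed-form Frechet means,
    affine-invariant (AIRM) counterparts with Karcher-mean iteration,
    unsupervised distribution alignment by Procrustes analysis in the
    log-domain (PA-LEM) and by Riemannian re-centering plus stretching
    (RPA-LEM and an AIRM baseline), a probabilistic learning vector
    quantization classifier with learnable log-domain metric tensor
    (PLVQ-LEML), a minimum-distance-to-Riemannian-mean baseline, an EEG
    epoch-to-covariance preprocessing pipeline, synthetic SPD data
    generators with controlled covariance shift, and evaluation protocols
    (balanced-class kappa, cross-session, cross-subject, CPU timing) with
    a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
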