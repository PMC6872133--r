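Package: seedmorph
Title: Seed Contour Morphometrics, Genomic Prediction and GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies seed shape from binary images or traced contours and
    links the resulting morphometric traits to genome-wide markers. Contours
    are cleaned, traced as eight-direction Freeman chain codes, resampled to
    equally spaced pseudo-landmarks and standardized by one of four
    direction/scale procedures (simple landmarks, generalized Procrustes
    superposition, or first-harmonic ellipse alignment with either start
    convention). Shape is described by elliptic Fourier descriptors or by the
    superposed point coordinates themselves, summarized by principal
    component analysis with contour reconstruction at the PC extremes, and
    fed to genomic prediction (GBLUP and multi-kernel Gaussian RKHS under
    repeated 10-fold cross-validation, scored by a contour-level Q2
    statistic) and to a Q+K mixed-model genome-wide association scan with
    Benjamini-Hochberg control. A synthetic genotype-to-shape simulator with
    known QTL and heritabilities makes the whole pipeline testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    EBImage,
    ape
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite,
    png,
    tiff,
    cluster,
    withr,
    vcfR
Config/testthat/edition: 3
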