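Package: florasym
Title: Geometric Morphometrics of Biradial Corolla Shape Symmetry
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Landmark-based geometric morphometric toolkit for analysing
    the biradial (four-fold) symmetry of tetrameric flower corollas.
    Provides TPS landmark input/output with arc-length outline resampling,
    the Klein four-group of reflection-with-relabelling symmetry
    transformations, generalized Procrustes analysis with bending-energy
    sliding of semilandmarks, principal-component decomposition of shape
    space into symmetric, laterally asymmetric and transversally
    asymmetric subspaces, nested permutation Procrustes ANOVA, Goodall's F
    regression, a Levene-analogue test of multivariate dispersion,
    non-metric multidimensional scaling, and a synthetic corolla outline
    generator with a nested sampling design for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
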