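Package: diffsaxs
Title: Difference X-Ray Solution Scattering Analysis of Protein Conformational Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for interpreting time-resolved difference X-ray solution
    scattering (SAXS/WAXS) from photoreceptor proteins. Predicts solution
    scattering curves from coordinate models with the Debye equation, scores
    every pair of candidate conformers from two state ensembles against an
    experimental difference curve by scale-optimised least squares, maps the
    residuals onto hinge-bend and twist (dihedral) conformational coordinates,
    decomposes time series of difference curves into early and late basis
    patterns with exponential half-time fits, and reduces raw detector images
    to normalised difference curves. Includes generators for fully synthetic
    test data: bead-model conformer ensembles with a planted bend and twist,
    noisy difference curves, two-component kinetic series, and detector
    images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
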