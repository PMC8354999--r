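Package: phacr
Title: Homotopic Co-Alteration Mapping from Coordinate-Based Meta-Analytic Foci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds maps of pathological homotopic anatomical co-alteration
    (PHAC) and meta-analytic homotopic connectivity (MHC) from tables of
    stereotactic alteration or activation foci. Each experiment's foci are
    turned into a modeled alteration (MA) probability volume with a Gaussian
    kernel whose width follows the full-width at half-maximum, compensated
    near the interhemispheric midline, thresholded and summarised over a
    mirror-symmetric parcellation into a binary experiments-by-nodes
    alteration matrix. Per homotopic pair of regions the package computes
    Patel's kappa with a Dirichlet-multinomial Monte Carlo significance test
    and Patel's tau for directionality, renders the statistics back into
    brain volumes, decomposes them over large-scale network labels, and
    assesses robustness by jackknife quadratic error and bootstrap
    resampling. A synthetic-data generator with known ground truth makes the
    whole pipeline testable without access to restricted databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
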