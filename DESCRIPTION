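Package: spotdecon
Title: Single-Cell Resolution Decomposition of Spatial Transcriptomics Spots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Resolves multi-cell spatial transcriptomics spots to single-cell
    resolution by integrating an annotated single-cell reference. Assigns a
    cell-type label to every segmented cell in every spot by maximum a
    posteriori estimation under a Poisson observation model with gene- and
    spot-level platform effects and a Potts smoothness prior, optimised by
    pairwise iterated conditional modes. Decomposes batch-corrected spot
    expression into per-cell expression profiles by annealed Langevin
    posterior sampling under a conditional score-based generative prior
    learned from the reference by denoising score matching; the same sampler
    corrects dropouts in sparse high-resolution data and imputes unmeasured
    genes in imaging-based data. Includes a synthetic-data generator that
    grids and aggregates reference cells into spots with known platform
    effects, spatially coherent labels and binomial capture-rate thinning,
    plus analytic Gaussian score oracles for exact validation of the samplers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    pracma,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
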