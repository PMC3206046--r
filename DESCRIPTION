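Package: bindkd
Title: Bayesian Estimation of Sequence-Specific Dissociation Constants
    from Paired Pre-Bound/Bound Sequencing Counts
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates sequence-specific dissociation constants (Kd),
    position-specific binding energies, and the free transcription-factor
    concentration from sequencing counts of a DNA ligand pool taken before
    and after equilibrium binding to a transcription factor.  Inference is
    by Metropolis-Hastings MCMC over multinomial count likelihoods, with an
    optional additive binding-energy model whose position-specific terms
    are selected by reversible-jump moves, an order-m Markov model of
    ligand synthesis frequencies, a forward simulator of pooled binding
    experiments, and accuracy metrics for evaluating experimental designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
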