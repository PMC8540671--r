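Package: vaemses
Title: VAE-Driven Multiscale Enhanced Sampling for Two-State Protein Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Learns a low-dimensional latent representation of two-state
    protein conformational ensembles from inter-domain C-alpha distances
    using a variational autoencoder, generates interpolated or extrapolated
    restraint schedules in the latent space, and drives Hamiltonian
    replica-exchange Langevin dynamics of a bead-model system with those
    schedules, recovering unbiased free-energy surfaces from the uncoupled
    replica.  Also provides Motion Tree domain decomposition by hierarchical
    clustering of inter-residue distance fluctuations, domain principal
    component analysis, free-energy-surface estimation, and a two-domain
    bead-protein generator so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    ape,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
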