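Package: stabmec
Title: Protein Stability Changes from Well-Tempered Metadynamics and
    Maximum-Entropy Reweighting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts the sign and magnitude of protein unfolding
    free-energy changes (ddG, hence the sign of the melting-temperature
    shift) under single-point mutations.  Implements a hydrogen-bond
    collective variable on protein structures, a well-tempered altruistic
    multiple-walkers metadynamics engine with a toy Langevin sampler,
    maximal-constrained-entropy (MEC) reweighting of the resulting
    metastatistics, and a mean-field MM/PBSA effective energy
    (Shrake-Rupley solvent-accessible surface area and a finite-difference
    linearized Poisson-Boltzmann solver), assembled into an end-to-end
    ddG pipeline with synthetic-data generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
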