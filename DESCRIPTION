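Package: evcont
Title: Eigenvector Continuation of Many-Electron Wave Functions Across Molecular Geometries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variational interpolation ("eigenvector continuation") of full
    configuration interaction wave functions across molecular geometries.
    Training wave functions are expressed in a symmetrically (Loewdin)
    orthogonalized atomic-orbital basis so that their probability amplitudes
    transfer between geometries; geometry-agnostic transition two-body reduced
    density matrices and overlaps then reduce inference at any test geometry to
    a small generalized eigenvalue problem with mean-field cost. The package
    includes a contracted-Gaussian integral engine for s and p shells with
    analytic nuclear derivatives, a determinant-space FCI solver with a direct
    Davidson sigma build, analytic forces for the continued state (including
    the Pulay term from the orthogonalizer), Born-Oppenheimer molecular
    dynamics (NVE velocity Verlet and Berendsen NVT), and active learning of
    training geometries via a Hamiltonian distance metric.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
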