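Package: gomartini
Title: Structure-Based Go-MARTINI Topologies and Coarse-Grained Trajectory Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds native-contact maps for coarse-grained structure-based
    (Go-type) protein models using a simple heavy-atom minimum-distance cutoff
    scheme, converts them into Go-MARTINI Lennard-Jones pair terms,
    secondary-structure-dependent backbone angle terms and elastic-network
    bonds, and writes GROMACS-dialect topology include files. Also provides
    the trajectory statistics used to validate such models: Kabsch
    superposition, per-residue RMSF, covariance PCA, RMSIP subspace overlap,
    fraction of native interface contacts (Q_AB) and selection minimum-distance
    time series, together with deterministic synthetic structure and ensemble
    generators for testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
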