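Package: mtassoc
Title: Association of Dynein Microtubule-Binding Domains with Microtubules
    Bearing Disordered E-Hook Tails
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how a compact, positively patched binder
    domain (such as the dynein microtubule-binding domain) associates with a
    charged filament decorated with intrinsically disordered acidic tails
    (tubulin E-hooks). Provides structure handling and model building
    (extended-tail construction, rigid transforms, perpendicular offset
    protocols, fixed-pKa ionization), a synthetic ensemble generator with
    planted distance-dependent contact and fluctuation statistics,
    heavy-atom contact counting and segment-level aggregation, Kabsch
    superposition with RMSD/RMSF profiles and linear trend fits,
    Daura (GROMOS-style) RMSD clustering with bound/free cross-state
    matrices, molecular-mechanics/generalized-Born binding-energy
    decomposition, and a finite-difference linearized Poisson-Boltzmann
    solver with surface-potential mapping and electrostatic field-line
    tracing. All analysis results are returned as tibbles so pipelines
    compose with tidyverse verbs.
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
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
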