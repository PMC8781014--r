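Package: allodeck
Title: Allosteric Site Discovery and Per-Residue Docking Score Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for allosteric-site discovery on GPCR-like receptors:
    an empirical five-term protein-ligand scoring function with per-residue
    energy decomposition (nine binding-recognition vectors), Monte-Carlo
    pose search with local refinement, geometric cavity detection combined
    with elastic-network motion-correlation z-scoring against a declared
    orthosteric pocket, a multi-method multi-complex consensus rule, and an
    MM-PBSA-WSAS component-table layer that reconstructs free-energy totals,
    ranks candidate sites and classifies allosteric modulators as positive
    or negative (PAM/NAM). Includes a deterministic synthetic-fixture
    generator (planted-cavity receptors, toy ligands) so every stage is
    testable offline, plus packaged free-energy component tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
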