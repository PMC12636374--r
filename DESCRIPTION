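Package: screenkit
Title: Consensus Toolkits for Ensemble-Based Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three tidy toolkits that automate the structure and ligand
    handling stages of an ensemble-based virtual-screening campaign against
    flexible protein targets. The ensemble toolkit reads multi-model NMR
    structures, superposes them by least-squares (Kabsch) fitting, computes
    pairwise backbone RMSD matrices, radius of gyration and per-residue
    RMSF, flags conformational outliers by consensus of three orthogonal
    detectors (IQR, isolation forest, Ward singleton analysis), selects the
    cluster number by internal validity indices, clusters with k-means, and
    picks quality-scored representative conformers by multi-method voting.
    The ligand-preparation toolkit standardizes, neutralizes, filters
    (Lipinski, drug-likeness, structural alerts) and de-duplicates SMILES
    libraries into screening-ready SDF files with full rejection logs. The
    hit-ranking toolkit aggregates docking scores and MM-GBSA binding
    energies through five complementary ranking strategies (z-score,
    percentile, weighted z-score, Pareto frontier peeling, strict dual
    cutoff) into a consensus ensemble rank. A synthetic-fixture generator
    with planted ground truth makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: OpenBabel (obabel on the PATH) for the
    ligand-preparation toolkit.
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
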