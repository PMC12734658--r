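Package: fragmatrix
Title: Design, Profiling, and Chemical-Space Novelty Analysis of
    Stereodefined Heterocyclic Fragment Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing fragment libraries built on
    saturated heterocycles. Enumerates a stereochemically explicit design
    matrix (scaffold x substitution pattern x relative configuration x aryl
    group x polar head group) from a declarative configuration, assembles
    isomeric SMILES for every design, profiles libraries against Rule-of-3
    physicochemical limits with racemate-aware descriptor calculation
    (Wildman-Crippen cLogP, Ertl TPSA, Lipinski H-bond counts, rotatable
    bonds), and quantifies structural novelty against comparator collections
    via Morgan fingerprints, Tanimoto nearest-neighbour statistics, seeded
    2D embeddings (UMAP/PCA) and silhouette separation scores. Includes a
    deterministic decoy-library generator for benchmarking and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    cluster,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    uwot,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
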