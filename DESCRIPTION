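Package: cgdock
Title: Coarse-Grained Flexible Protein-Protein Docking by Replica Exchange
    Monte Carlo
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A coarse-grained flexible protein-protein docking simulator. Protein
    chains are reduced to C-alpha traces on a fine cubic lattice with derived
    pseudo-atoms (C-beta, united side chain, peptide-bond center), sampled by
    Replica Exchange Monte Carlo with simulated annealing over a temperature
    ladder with geometrically increasing increments. A two-tier flat-bottom
    distance-restraint scheme keeps the receptor near-rigid while the ligand
    translates, rotates and refolds around it. Pooled models are post-processed
    by receptor-ligand contact-map computation, contact-count filtering,
    complete-link hierarchical clustering under the Jaccard distance, and
    density ranking; model quality is scored with CAPRI-style metrics (iRMSD,
    LRMSD, LoRMSD, fNAT, RMSF). Includes a synthetic toy-complex generator so
    the whole pipeline runs without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    ggplot2,
    jsonlite,
    Matrix,
    parallel,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
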