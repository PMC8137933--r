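Package: cppforge
Title: Generation and Mechanistic Prioritization of Cell-Penetrating Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for discovering candidate cell-penetrating
    peptides (CPPs). Recurrent (GRU) sequence generation trained on known
    penetrating peptides, a max-pooling recurrent permeability predictor,
    redundancy filtering of training sets, a one-dimensional steered-Langevin
    surrogate of membrane-crossing pulling simulations, mechanistic scoring of
    replica maximum steering forces by sample variance penalization, and a
    composition-preserving shuffled-sequence null analysis with BLOSUM62
    center-star alignment, consensus/occupancy/quality profiling and motif
    extraction. Readers and writers for FASTA sequence files and two-column
    steering-force traces (GROMACS pullf xvg dialect) let real pulling output
    be ranked by the same machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
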