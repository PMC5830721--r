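Package: disulfidr
Title: Mining and Characterizing Labile Disulfide Bonds in Protein X-Ray Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies candidate allosteric ("labile") disulfide bonds by
    harvesting SSBOND annotations from collections of legacy-format PDB
    X-ray structures, mapping bonded cysteines onto canonical protein
    sequences, and flagging bonds that are present in some structures of a
    protein but validly absent in others. Every bond is characterized
    geometrically: the five chi dihedral angles, the two alpha bending
    angles at the sulfurs, the sulfur-sulfur distance, the dihedral strain
    energy, the 20-way sign-based configuration class, the 12-atom B-factor
    average and the secondary-structure context. Includes a deterministic
    synthetic-structure generator for ground-truth validation and cohort
    statistics comparing labile bonds against a reference set.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    withr,
    yaml,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
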