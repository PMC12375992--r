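Package: hydrophobinr
Title: Hydrophobin Sequence Profiling and Structure Model Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for large-scale characterization of fungal hydrophobins.
    Reads FASTA sequence sets and PDB coordinate files into tidy tibbles;
    computes physicochemical profiles (length, cysteine count, Kyte-Doolittle
    GRAVY, Bjellqvist isoelectric point, residue composition); detects the
    eight-cysteine hydrophobin motif with its intercysteine loop nomenclature
    and classifies sequences into class I or class II by cysteine spacing;
    mines non-canonical features (ten-cysteine five-disulfide candidates,
    extended N-terminal tails, polyhydrophobins); benchmarks predicted
    structure models against experimental ensembles with Kabsch superposition
    Calpha RMSD, TM-score and lDDT-Calpha; maps disulfide topology against
    the canonical C1-C6/C2-C5/C3-C4/C7-C8 pattern; computes Shrake-Rupley
    solvent-accessible surface area; and clusters structures into clades via
    pairwise TM-score distances and UPGMA trees with Newick output. A seeded
    synthetic-data generator produces sequence corpora with planted features
    and structure pairs under controlled coordinate noise, so every stage of
    the pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    ape,
    Biostrings,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    bio3d,
    withr
Config/testthat/edition: 3
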