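Package: sitegraft
Title: Homology-Based Transfer of Ligand-Binding Sites onto Predicted
    Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts substrate-binding residues on a predicted protein
    structure by structural homology: parses chemical-component
    dictionaries and profile-HMM hit tables, screens ligands by MACCS
    structural-key Tanimoto similarity, trims low-confidence termini of
    predicted models using per-residue pLDDT, superposes ligand-bound
    homolog structures with an identity-gated alignment mode and
    iterative Kabsch fitting with outlier rejection, transfers homolog
    ligands into the query frame with contact and clash analysis, and
    compares missense-variant models against the wild type. Ships
    annotation tables and synthetic-fixture generators for the human
    COQ2 prenyltransferase case study.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    BiocGenerics,
    Biostrings,
    ChemmineOB,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
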