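Package: crestpocket
Title: Protein-Ligand Binding Pocket Preparation for CREST Conformer Sampling
Version: 0.1.0
Authors@R:
    person("crestpocket", "developers", email = "crestpocket@example.org",
           role = c("aut", "cre"))
Description: Carves a chemically consistent binding pocket around a posed
    ligand, starting from a protein PDB file and a ligand TRIPOS MOL2 file.
    The pocket is selected by iterative distance shells around the ligand,
    completed to full residues, extended with capping atoms, cleaned of
    isolated atoms and disconnected residues, protonated at physiological pH,
    and merged with the ligand.  The package then emits constrained input
    files for the external CREST conformer-rotamer ensemble sampling program,
    optionally runs it, and re-annotates the resulting conformers with the
    template residue metadata.  A deterministic synthetic complex generator
    and brute-force geometric oracles make the whole pipeline testable
    without external downloads or binaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
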