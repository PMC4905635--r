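Package: dimerdx
Title: Discriminating Alternative Protein Dimer Models by Interface
    Energetics and Rank Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding which of two alternative structural models of a
    protein-protein dimer is the more plausible dimerization mode. Provides a
    light-weight coordinate model with PDB input/output, Kabsch superposition,
    loop grafting and in-silico point mutagenesis; Shrake-Rupley solvent
    accessible surface area and interface characterization (buried surface,
    interface residues, typed electrostatic and van der Waals contacts); a
    single-trajectory implicit-solvent (generalized Born / surface area)
    binding free energy engine with per-residue and residue-pairwise
    decomposition; Rank Products comparison of per-residue binding
    contributions between two models with permutation e-values and
    differential-contribution signatures; empirical and alanine-scanning
    hot-spot prediction; rule-based design of model-discriminating point
    mutations; and generators for synthetic toy dimers, decoy orientations and
    simulated replicate matrices used as a self-contained test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ggplot2,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
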