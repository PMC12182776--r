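Package: epimap
Title: Consensus Epitope Mapping from Antibody-Antigen Docking Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-docking analysis of ranked antibody-antigen pose ensembles.
    Reads and writes PDB structures, performs sequence-alignment-guided
    rigid-body superposition (Kabsch) with iterative outlier rejection,
    detects interface residues at configurable distance cutoffs, types
    intermolecular contacts by side-chain polarity, finds hydrogen bonds and
    salt bridges geometrically, computes Shrake-Rupley solvent-accessible
    surface area, and estimates binding free energy and dissociation
    constants from a configurable contact-based linear model. The core
    statistic is the per-residue contact frequency across the top-ranked
    docking models, from which consensus epitope lists, Venn overlaps,
    cross-combination shared-residue matrices and spatially clustered
    candidate binding sites are derived. A synthetic-data module generates
    toy receptors and docking ensembles with planted epitopes for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    data.table,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
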