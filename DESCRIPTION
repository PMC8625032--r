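Package: templig
Title: Template-Guided Prediction of Ligand Binding Modes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing and predicting small-molecule binding modes
    in protein pockets from template complex structures. Implements an
    intercomparison strategy that superimposes conformer ensembles of a query
    ligand onto co-crystallized template ligands using a hybrid 3D similarity
    (Gaussian shape overlap plus pharmacophore feature matching), refines the
    superimposed pose against the rigid receptor with an empirical
    protein-ligand scoring function, and re-ranks candidate poses with a
    hybrid score combining the binding score and the 3D similarity. Includes
    symmetry-aware maximum-common-substructure RMSD evaluation, dataset
    curation filters (covalent links, pocket multiplicity, size, molecular
    weight, solvent-accessible-surface-area burial), per-protein template
    library assembly, all-versus-all intercomparison statistics, and a nested
    bootstrap estimator of the minimum number of templates required to cover
    a binding mode. A deterministic synthetic fixture generator provides toy
    ligands and pockets so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    ChemmineR
SystemRequirements: Python 3 with RDKit (python on the PATH) for SMILES
    parsing, canonicalization and 3D conformer embedding
Config/testthat/edition: 3
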