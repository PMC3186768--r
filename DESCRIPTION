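Package: pgpsub
Title: P-Glycoprotein Substrate Classification with Topological Descriptors and RBF-SVM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies small molecules as P-glycoprotein substrates or
    non-substrates from 2D molecular-graph descriptors. Provides
    hydrogen-suppressed molecular graph parsing (SMILES and SDF/MOL V2000),
    Broto-Moreau topological autocorrelations, Burden-matrix eigenvalue
    descriptors, edge-adjacency eigenvalues and spectral moments, F-score
    feature ranking with correlation pruning and incremental selection, a
    grid-searched RBF-kernel support vector machine with a repeated-split
    (100-run) evaluation protocol, a diversity-based external-validation-set
    constructor, and confusion-matrix statistics (accuracy, sensitivity,
    specificity, Matthews correlation coefficient).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    ChemmineR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
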