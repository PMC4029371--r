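Package: kcfs
Title: KEGG-Style Atom Typing and Interpretable Biochemical Substructure Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts MDL Molfile/SDF chemical structures into KEGG-atom-typed
    molecular graphs (KCF), enumerates seven classes of interpretable
    biochemical substructures with canonical string labels (KCF-S), and
    provides the downstream analyses built on those descriptors:
    weighted-Jaccard similarity with quasi-clique agglomerative clustering,
    Fisher's exact characteristic-substructure ranking between molecule sets,
    and an L1-regularized linear support vector machine that predicts the
    enzymatic-reaction likeness of ordered compound pairs from
    common/differential count-vector features.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
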