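# kcfs

Interpretable chemical substructure descriptors for biochemistry: KEGG-style
atom typing, KCF/KCF-S flat files, and the analyses built on them.

Biochemists reason about molecules through named functional groups — amide
bonds, phenolic hydroxyls, pyranose rings — while conventional chemical
fingerprints encode anonymous bits. `kcfs` converts MDL Molfile/SDF
structures into graphs whose atoms carry one of 68 three-character KEGG atom
types (`C1a` methyl, `C6a` carboxylate carbon, `N4y` aromatic tertiary
amine, ...), then enumerates seven classes of substructures with canonical,
human-readable string names:

| attribute | what it is | example |
|---|---|---|
| ATOM | each typed heavy atom | `C6a` |
| BOND | each edge, labels sorted | `C5a-N1b` (amide bond) |
| TRIPLET | two edges sharing a center | `C6a-C1c-N1a` (alpha-amino acid) |
| VICINITY | an atom with its full shell (degree >= 3) | `C8y(C8x+C8x+O1a)` |
| RING | SSSR rings and condensed (fused-perimeter) rings | `C8x-N4y(C1y)-C8y-C8y-N5x` |
| SKELETON | carbon backbones with annotations | `C1a-C1c(C1a)-C1b-C1c(N1b)-C5a(N1b+O5a)` |
| INORGANIC | non-carbon components | `O1c-P1b(O2b(C1b))(O1c)-O1c` |

The per-molecule counts of these strings form the KCF-S descriptor
`Phi(C)`. On top of it the package provides:

* **Similarity and clustering** — weighted Jaccard
  `J(x,y) = sum_i min(x_i,y_i) / sum_i max(x_i,y_i)` and quasi-clique
  agglomerative clustering (clique ratio `r`, threshold `t`; `r = 1` is
  exactly complete linkage cut at `t`).
* **Characteristic substructures** — one-sided Fisher's exact ranking of
  strings enriched in one molecule set versus another.
* **Enzymatic-reaction likeness** — ordered compound pairs featurized as
  `(Phi(C) ^ Phi(C'), Phi(C) (-) Phi(C'), Phi(C') (-) Phi(C))`
  (elementwise min and positive difference; "diff-common", or the two
  difference blocks only, "diff-only") and classified with an
  L1-regularized squared-hinge linear SVM, evaluated by 5-fold
  cross-validated AUC/AUPR against a weighted-Jaccard baseline.

Twenty built-in molecules and a rule-based synthetic reaction-pair
generator (methylation, phosphorylation, oxidation, amide hydrolysis,
cyclization) make every part testable offline.

## Worked example

```r
library(kcfs)

cpd <- extractSubstructures(kcfCompound(builtinMolecule("adenosine")))
cpd
#> KcfCompound 'adenosine' (Compound): 19 atoms typed
#>   labels: C1yx4 C8yx3 N5xx3 O1ax3 C8xx2 C1bx1 N1ax1 N4yx1 O2xx1
#>   substructure instances: ATOM=19 BOND=21 RING=4 SKELETON=2 TRIPLET=31 VICINITY=8

s <- substructures(cpd)
s$canonical[s$attribute == "RING"]
#> [1] "C1y(C1b)-C1y(O1a)-C1y(O1a)-C1y(N4y)-O2x"
#> [2] "C8x-N4y(C1y)-C8y-C8y-N5x"
#> [3] "C8x-N5x-C8y(N1a)-C8y-C8y-N5x"
#> [4] "C8x-N4y(C1y)-C8y-N5x-C8x-N5x-C8y(N1a)-C8y-N5x"
```

The four RING entries are the ribofuranose ring, the imidazole and
pyrimidine component rings of the purine, and the 9-membered condensed
purine entry (its `(C1y)` branch is the ribose attachment at N9, `(N1a)`
the exocyclic amine).

```r
d  <- buildDescriptor(cpd, level = 3)
d
#> KcfsDescriptor (k3): 55 distinct keys, total count 85

d2 <- buildDescriptor(extractSubstructures(kcfCompound(builtinMolecule("adenine"))))
weightedJaccard(d, d2)
#> [1] 0.3333333
```

Adenosine and free adenine share exactly one third of their counted
substructure mass: the purine core is conserved while every
ribose-containing string differs.

A command-line front end wraps the same functions:

```sh
kcfs convert --in mols.sdf --out out.kcfs --format kcfs
kcfs cluster --in mols.sdf --t 0.7 --r 0.7 --out clusters.tsv
kcfs enrich  --set-a a.sdf --set-b b.sdf --top 5
kcfs train   --in mols.sdf --pairs positives.tsv --mode diff-common --out model.tsv
```

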