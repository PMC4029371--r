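---
title: "KCF-S descriptors: model, conventions and design choices"
author: "kcfs package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{KCF-S descriptors: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kcfs)
```

## The representation

Biochemists describe molecules through named functional groups — amide
bonds, phenolic hydroxyls, pyranose rings — while most machine-readable
chemical descriptors are opaque bit strings. This package implements an
integer-count descriptor whose every dimension *is* such a named group.

A molecule enters as an MDL Molfile V2000 (or SDF) and becomes a
hydrogen-suppressed graph: heavy atoms are vertices, bonds with explicit
kekulized orders 1/2/3 are edges. Each heavy atom receives one of 68
three-character **KEGG atom types** (e.g. `C1a` methyl carbon, `C6a`
carboxylate carbon, `N4y` aromatic tertiary amine nitrogen, `O2b`
phosphate-ester oxygen). The first character is the element family, the
first two the atom class, all three the full type — so each label carries a
three-level hierarchy, addressed as resolution levels k1/k2/k3.

Seven classes of substructure are then enumerated, each instance named by a
canonical string built from the atom type labels:

* **ATOM** — every heavy atom (its label at level k).
* **BOND** — every edge; the two labels sorted and hyphen-joined
  (`C5a-N1b` is an amide bond).
* **TRIPLET** — every pair of edges sharing a center; flank labels sorted
  around the center (`C6a-C1c-N1a` is the alpha-amino-acid motif).
* **VICINITY** — every atom of heavy degree at least 3 with its full
  neighbor shell (`C8y(C8x+C8x+O1a)` is an unsubstituted phenolic
  hydroxyl).
* **RING** — every SSSR ring of 3–12 atoms, plus one *condensed* entry per
  ortho-fused ring system whose perimeter is a single cycle of at most 12
  atoms covering the whole system (purine appears both as its 5- and
  6-membered component rings and as a 9-membered condensed entry).
* **SKELETON** — every connected carbon component of at least two carbons:
  a longest carbon path as backbone, remaining carbons bundled as nested
  branches, heteroatom neighbors annotated one shell deep.
* **INORGANIC** — every connected non-carbon component of at least two
  atoms, rendered like SKELETON with carbon neighbors as annotations
  (`O1c-P1b(O2b(C1b))(O1c)-O1c` is a primary-alcohol orthophosphate).

The counts of all canonical strings form the **KCF-S descriptor**; the
typed graph and the enumerated instances can be serialized to the KCF and
KCF-S flat-file formats.

## Perception model

**Rings.** The ring basis is an SSSR: the shortest cycle through every edge
is collected and a maximal GF(2)-independent subset of size
(bonds − atoms + components) is kept, smallest cycles first. Rings sharing
at least one bond are grouped into fused systems. Rings larger than 12
atoms keep their ring-membership flags but produce no RING entries.

**Aromaticity.** A 5-, 6- or 7-membered SSSR ring is aromatic when every
ring atom either takes part in a double bond or is an N/O/S contributing a
lone pair, and the π count satisfies 4n+2 (2 per in-ring double bond, 2 per
lone pair). An atom whose double bond points at another atom *of the same
fused system* contributes 1. The last rule makes perception independent of
which kekulé structure a fused heteroaromatic was drawn with — the
imidazole ring of a purine is aromatic whether the fusion bond or the
flanking bonds carry the double bonds. Rings are judged one at a time; an
atom is aromatic if any of its rings is.

**Atom typing.** Rules are ordered most-specific-first within each element;
carbons are typed before heteroatoms so that oxygen and nitrogen labels can
refer to the carbon context (ester oxygens mirror their `C7a` carbon).
Deliberate conventions, chosen so that drawing conventions and protonation
states do not change the descriptor:

* Terminal oxygens on phosphate phosphorus are always `O1c` and on
  sulfonate/sulfate sulfur always `O1d`, whether drawn as P=O/S=O or
  P–OH/S–OH.
* A carboxylate anion types exactly like the acid (`C6a`/`O6a`).
* A lone methane carbon is `C1a` and a lone water oxygen `O0`: "R" in a
  terminal pattern is read as "hydrogen or heavy atom", undefined
  otherwise.
* Sp2 ring carbons are `C8x/C8y` only when their ring is perceived
  aromatic; otherwise they fall back to `C2x/C2y`.

## Canonical strings

A substructure string is a backbone (path or cycle) of labels joined by
`-`, with parenthesized substituent groups per backbone atom. The canonical
representative is the byte-wise smallest rendering over all admissible
traversals: every rotation in both directions for cycles, both directions
for paths. Byte-wise comparison (C locale) is used everywhere so output
does not depend on the session locale.

Substituent grammar, frozen by golden-file tests: single-atom substituents
of one backbone atom form one `(a+b+c)` group with members sorted; each
multi-atom branch is rendered recursively into its own group; groups are
ordered by decreasing rendered length, ties alphabetically. For SKELETON
and INORGANIC backbones, ties among equally long backbone paths are broken
first on the bare label sequence and then on the full rendering — this is
what places the two plain hydroxy oxygens of a phosphate on the backbone
(`O1c-P1b(O2b(C1b))(O1c)-O1c`) rather than the ester oxygen, matching the
conventional rendering of these groups. RING branches are the heavy
neighbors outside the ring's fused system, one shell deep, so component
rings of a fused system are not decorated with each other's atoms.

Descriptor levels below k3 truncate the per-atom labels *first* and then
re-canonicalize every instance through the same machinery, so k1/k2 strings
are properly re-sorted; instance totals per attribute are conserved across
levels (a tested invariant).

## The KCF-S flat file

Sections use 12-character left-justified keys, single-space-separated
fields, 4-decimal coordinates, continuation lines indented 12 spaces and a
`///` terminator. The SUBSTR section lists the seven subsections in fixed
order with the number of distinct strings; each entry line gives the
string, its count in parentheses, and the 1-based, ascending,
comma-separated atom lists of its instances, semicolon-separated. Rendering
is deterministic, so equal documents are byte-identical — the round-trip
tests require bit-exactness.

## Similarity, clustering, enrichment

The similarity of two descriptors is the **weighted Jaccard coefficient**
$J(x, y) = \sum_i \min(x_i, y_i) / \sum_i \max(x_i, y_i)$ over the key
union; two empty descriptors compare as 1 by convention. $1 - J$ is a
metric, which the suite spot-checks on random triples.

Quasi-clique clustering (QCC) agglomerates greedily over a similarity
matrix with two parameters: the similarity threshold $t$ and the clique
ratio $r$. A cluster pair is admissible when at least a fraction $r$ of its
cross pairs have similarity $\ge t$; among admissible pairs the one with
the highest *minimum* cross similarity is merged (ties: higher mean,
smaller combined size, smallest member index). The min-first order was a
genuinely open choice; it was selected because it makes $r = 1$ *exactly*
complete-linkage clustering cut at $t$ (monotone merge heights), a
documented equivalence that the suite verifies against `hclust`. A
mean-first order can provably diverge from complete linkage through
blocking merges.

Characteristic substructures of a molecule set A versus a set B are ranked
by the one-sided Fisher's exact test on the 2×2 presence table (presence
means count ≥ 1); raw p-values rank the output, with an optional
Benjamini–Hochberg column that is off by default.

## Reaction likeness

An ordered compound pair $(C, C')$ is featurized from the projected count
vectors $\Phi(C), \Phi(C')$ with two operations, elementwise minimum
(common features) and positive difference (directional change):
diff-common $= (\Phi(C) \wedge \Phi(C'),\ \Phi(C) \ominus \Phi(C'),\
\Phi(C') \ominus \Phi(C))$ of length $3D$, and diff-only (the two
difference blocks) of length $2D$. The classifier is a linear SVM with
squared-hinge loss and L1 regularization,
$\min_w \|w\|_1 + C \sum_i \max(0, 1 - y_i(w^\top x_i + b))^2$, solved by
FISTA proximal gradient with a power-iteration Lipschitz estimate and an
unpenalized intercept (default 2000 iterations, relative objective
tolerance 1e-9 checked every 20 iterations — converged long before the cap
on the problem sizes used here). The L1 penalty keeps the weight vector
sparse and therefore readable: nonzero weights name substructure changes.
An L2 variant exists for the sparsity comparison. The no-learning baseline
scores a pair by the weighted Jaccard of its two descriptors.

Cross-validation is pair-level: seeded shuffling assigns every pair to
exactly one of five test folds. The feature space (the key list defining
$D$) is built once from the whole compound corpus — labels play no role in
it and the published experiments likewise use a fixed corpus-wide vector
dimension. The regularization constant is selected per fold from the grid
{0.01, 0.1, 1, 10} by AUPR on a held-out fifth of the training pairs.
Performance is summarized by pooled AUC (trapezoidal ROC; the suite checks
agreement with the Mann–Whitney formulation to 1e-10) and AUPR (stepwise
precision–recall area).

## The synthetic benchmark

Nothing needs to be downloaded: 20 built-in molecules (alcohols, aromatics,
amino acids and peptide fragments, sugars, a phosphate, a sulfonate,
purines) ship as plain-text Molfiles, and a rule-based generator emulates
enzymatic transformations — O-methylation of alcohol hydroxyls,
phosphorylation, alcohol-to-carbonyl oxidation, amide hydrolysis and
intramolecular ether cyclization. Starting from the scaffolds (products may
serve as later substrates, so transformation chains form), each
substrate/product pair is emitted in both directions as a positive example;
a pair is accepted only if it conserves its core, operationalized as
weighted Jaccard ≥ 0.5 at k3. Negatives are drawn uniformly from all other
ordered pairs of the resulting compound set at 10 negatives per positive.
The default benchmark (seed 7) uses 60 directed positives and 600
negatives; this size keeps the whole evaluation, including the C grid,
within a few minutes on one CPU and is the size at which all frozen
expectations were set.

What the generator emulates — and what it does not: transformations are
localized edits on a conserved scaffold, so positive pairs have small,
rule-specific difference blocks, which is exactly the signal the pair
features expose. Real reactant-pair data differ in scale (thousands of
positives, tens of millions of candidate pairs), in chemistry
(rearrangements, multi-site changes, cofactor conventions) and in
negative-set composition. Two consequences matter for interpreting the
tests. First, with ~50 compounds, many negatives are trivially dissimilar,
so the weighted-Jaccard baseline is very strong on this benchmark — at this
scale a similarity heuristic can rank nearly as well as, or better than, a
model trained on 48 positives per fold, and the acceptance suite reports
exactly what it measures rather than assuming the large-scale ordering.
Second, passing the benchmark shows the pipeline learns localized
difference features; it does not certify performance on real metabolic
data.

## Numerical and degenerate-input choices

* Molfile charges: `M  CHG` lines, when present, discard all old-style
  atom-block charge codes (the V2000 rule); otherwise the old codes apply.
* Aromatic input bonds (type 4) are kekulized by backtracking; carbons
  must receive exactly one double bond, O/S none, N either — an
  N-containing ring drawn aromatic without hydrogen placement is resolved
  to the first consistent assignment in a fixed search order (tautomer
  choice is inherently ambiguous in that encoding). Unkekulizable input is
  an error.
* Fused systems whose perimeter is not a single covering cycle (bridged,
  spiro-linked aggregates) produce component RING entries only, with a
  warning for the skipped condensed entry.
* Empty molecules, single atoms, and molecules without carbons are all
  legal; extractors return empty sets rather than failing.
* In a triangle of identically labeled atoms, the three TRIPLET instances
  share one atom set and one string; they are still counted as three
  (centers differ), keeping the count identity
  $\sum \mathrm{TRIPLET} = \sum_v \binom{d_v}{2}$ exact. The flat file, in
  contrast, lists distinct atom lists per string.
* Random-molecule generation respects fixed valence caps (C 4, N 3, O 2,
  S 2, P 4) and is fully determined by its seed.

## Known limitations

* SSSR is one canonical choice of ring basis; tools enumerating larger
  ring sets will emit additional RING entries for polycyclics.
* The aromaticity model is a single-ring Hückel approximation with a
  fused-system correction; exotic mesoionic or charged aromatics may be
  typed as their non-aromatic fallbacks.
* SKELETON backbone enumeration is exponential in pathological carbon cages
  and is guarded by an enumeration cap; practical metabolites are far below
  it.
* The L1-SVM solver is a dense proximal-gradient method, adequate for
  thousands of pairs and features, not for tens of millions — full-scale
  reconstruction runs would need a sparse solver behind the same
  interface.
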