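# Ring/aromaticity perception and KEGG atom type assignment.

labels_of <- function(name) atomLabels(fixture_cpd(name))

test_that("the atom type catalog has exactly 68 unique labels", {
  cat <- keggAtomTypes()
  expect_equal(nrow(cat), 68L)
  expect_false(anyDuplicated(cat$label) > 0)
  # the shipped text table is the same catalog
  path <- system.file("extdata", "kegg_atom_types.tsv", package = "kcfs")
  expect_equal(nrow(utils::read.delim(path)), 68L)
})

test_that("labels truncate to k1/k2 and short labels are returned whole", {
  expect_equal(truncateLabel("C1y", 2), "C1")
  expect_equal(truncateLabel("C1y", 1), "C")
  expect_equal(truncateLabel("X", 3), "X")
  expect_equal(truncateLabel(c("C1y", "Z"), 2), c("C1", "Z"))
  expect_error(truncateLabel("C1y", 4), "k must be")
})

test_that("ring perception finds SSSR rings and fused systems", {
  benzene <- perceiveRings(builtinMolecule("benzene"))
  expect_length(benzene$rings, 1L)
  expect_length(benzene$rings[[1]], 6L)
  expect_length(benzene$fused, 0L)

  hexane <- perceiveRings(make_mol(rep("C", 6),
                                   cbind(1:5, 2:6, 1L), id = "n-hexane"))
  expect_length(hexane$rings, 0L)

  purine <- perceiveRings(builtinMolecule("adenine"))
  expect_equal(sort(lengths(purine$rings)), c(5L, 6L))
  expect_length(purine$fused, 1L)
  expect_length(purine$fused[[1]]$atoms, 9L)
})

test_that("aromaticity follows the Hueckel rule", {
  arom <- function(mol) {
    r <- perceiveAromaticity(mol, perceiveRings(mol))
    sum(r$aromatic)
  }
  expect_equal(arom(builtinMolecule("benzene")), 6L)
  expect_equal(arom(builtinMolecule("imidazole")), 5L)
  cyclohexene <- make_mol(rep("C", 6),
                          rbind(c(1, 2, 2), c(2, 3, 1), c(3, 4, 1),
                                c(4, 5, 1), c(5, 6, 1), c(6, 1, 1)))
  expect_equal(arom(cyclohexene), 0L)
  expect_equal(arom(builtinMolecule("cyclohexane")), 0L)
})

test_that("printed example molecules receive the published labels", {
  expect_equal(labels_of("ethanol"), c("C1a", "C1b", "O1a"))
  expect_setequal(labels_of("alanine"), c("C1a", "C1c", "C6a", "N1a", "O6a"))
  expect_equal(sort(table(labels_of("alanine"))[["O6a"]]), 2L)
  expect_equal(labels_of("benzene"), rep("C8x", 6))
  # methyl phosphate: P1b with three terminal O1c and one bridging O2b
  mp <- table(labels_of("methyl_phosphate"))
  expect_equal(mp[["P1b"]], 1L)
  expect_equal(mp[["O1c"]], 3L)
  expect_equal(mp[["O2b"]], 1L)
  # sulfonate sulfur with three O1d
  ms <- table(labels_of("methanesulfonate"))
  expect_equal(ms[["S4a"]], 1L)
  expect_equal(ms[["O1d"]], 3L)
})

test_that("amide bonds type as C5a-N1b", {
  lab <- labels_of("n_methylacetamide")
  expect_equal(sort(lab), sort(c("C1a", "C5a", "O5a", "N1b", "C1a")))
})

test_that("imidazole and purine atoms carry aromatic nitrogen labels", {
  expect_setequal(labels_of("imidazole"), c("C8x", "N4x", "N5x"))
  adenine <- table(labels_of("adenine"))
  expect_equal(adenine[["N5x"]], 3L)
  expect_equal(adenine[["N4x"]], 1L)  # free base: N9-H
  expect_equal(adenine[["N1a"]], 1L)  # exocyclic amine
  # N9-substituted adenine: the ring nitrogen becomes N4y
  adenosine <- table(labels_of("adenosine"))
  expect_equal(adenosine[["N4y"]], 1L)
})

test_that("terminal-type atoms fall back sensibly for bare molecules", {
  expect_equal(atomLabels(kcfCompound(make_mol("C"))), "C1a")    # methane
  expect_equal(atomLabels(kcfCompound(make_mol("O"))), "O0")     # water
  expect_equal(atomLabels(kcfCompound(make_mol(c("C", "Cl"),
                                               rbind(c(1, 2, 1))))),
               c("C1a", "X"))
  expect_equal(atomLabels(kcfCompound(make_mol(c("C", "Se"),
                                               rbind(c(1, 2, 1))))),
               c("C1a", "Z"))
})

test_that("every atom gets exactly one label and k1 counts match elements", {
  for (nm in all_fixture_names) {
    cpd <- fixture_cpd(nm)
    lab <- atomLabels(cpd)
    el <- atomTable(cpd)$element
    expect_length(lab, length(el))
    expect_true(all(nchar(lab) >= 1 & nchar(lab) <= 3), info = nm)
    fam <- truncateLabel(lab, 1)
    expected <- ifelse(el %in% c("F", "Cl", "Br", "I"), "X",
                 ifelse(el %in% c("C", "N", "O", "S", "P"), el, "Z"))
    expect_equal(fam, expected, info = nm)
  }
})

test_that("typing is invariant under atom reordering", {
  for (nm in c("adenosine", "leucine_dipeptide", "methyl_phosphate", "imidazole")) {
    mol <- builtinMolecule(nm)
    ref <- atomLabels(kcfCompound(mol))
    for (rep_i in 1:20) {
      set.seed(rep_i)
      perm <- sample(atomCount(mol))
      permuted <- permute_mol(mol, perm)
      lab <- atomLabels(kcfCompound(permuted))
      expect_equal(lab, ref[perm], info = paste(nm, rep_i))
    }
  }
})

test_that("charged nitrogen species type by spec rules", {
  # tetramethylammonium: N+ with four single bonds
  tma <- make_mol(c("N", "C", "C", "C", "C"),
                  cbind(1L, 2:5, 1L), charges = c(1L, 0L, 0L, 0L, 0L))
  expect_equal(atomLabels(kcfCompound(tma))[1], "N1d")
  # carboxylate anion is typed like the acid (protonation-insensitive)
  acetate <- make_mol(c("C", "C", "O", "O"),
                      rbind(c(1, 2, 1), c(2, 3, 2), c(2, 4, 1)),
                      charges = c(0L, 0L, 0L, -1L))
  expect_equal(atomLabels(kcfCompound(acetate)), c("C1a", "C6a", "O6a", "O6a"))
})
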