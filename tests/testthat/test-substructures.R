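# Canonical string generation and the seven substructure extractors.

test_that("canonical strings are rotation- and reflection-invariant", {
  expect_equal(canonicalLinearString(rep("C8x", 6), cyclic = TRUE),
               "C8x-C8x-C8x-C8x-C8x-C8x")
  ring_labels <- c("C8y", "C8x", "C8x", "C8x", "C8x", "C8x")
  att <- c(list("(C1a)"), rep(list(character(0)), 5))
  expect_equal(canonicalLinearString(ring_labels, att, cyclic = TRUE),
               "C8x-C8x-C8x-C8x-C8x-C8y(C1a)")
  # any rotation of the input gives the same canonical string
  for (s in 1:6) {
    rot <- ((seq_len(6) + s - 2) %% 6) + 1
    expect_equal(canonicalLinearString(ring_labels[rot], att[rot], cyclic = TRUE),
                 "C8x-C8x-C8x-C8x-C8x-C8y(C1a)")
  }
  expect_error(canonicalLinearString(character(0)), "empty backbone")
})

test_that("cycle canonicalization equals the exhaustive-traversal oracle", {
  pool <- c("C1x", "C1y", "C8x", "C8y", "N5x", "O2x", "S2x")
  for (seed in 1:40) {
    set.seed(seed)
    n <- sample(3:10, 1)
    labels <- sample(pool, n, replace = TRUE)
    att <- ifelse(runif(n) < 0.3, "(O1a)", "")
    got <- canonicalLinearString(labels, as.list(att), cyclic = TRUE)
    expect_equal(got, brute_traversal_min(labels, att, cyclic = TRUE),
                 info = paste("seed", seed))
    # path variant
    got_p <- canonicalLinearString(labels, as.list(att), cyclic = FALSE)
    expect_equal(got_p, brute_traversal_min(labels, att, cyclic = FALSE),
                 info = paste("path seed", seed))
  }
})

test_that("ATOM instances cover every heavy atom at the requested level", {
  cpd <- fixture_cpd("alanine")
  k3 <- extractAtoms(cpd@graph, atomLabels(cpd), 3)
  counts <- table(vapply(k3, `[[`, character(1), "canonical"))
  expect_equal(counts[["C1a"]], 1L)
  expect_equal(counts[["C1c"]], 1L)
  expect_equal(counts[["C6a"]], 1L)
  expect_equal(counts[["N1a"]], 1L)
  expect_equal(counts[["O6a"]], 2L)
  k1 <- extractAtoms(cpd@graph, atomLabels(cpd), 1)
  expect_equal(as.vector(table(vapply(k1, `[[`, character(1), "canonical"))),
               c(3L, 1L, 2L))
  expect_length(extractAtoms(make_mol(character(0)), character(0)), 0L)
})

test_that("BOND strings sort the two labels alphabetically", {
  cpd <- fixture_cpd("ethanol")
  bonds <- vapply(extractBonds(cpd@graph, atomLabels(cpd)), `[[`,
                  character(1), "canonical")
  expect_setequal(bonds, c("C1a-C1b", "C1b-O1a"))
  nma <- fixture_cpd("n_methylacetamide")
  expect_true("C5a-N1b" %in% vapply(extractBonds(nma@graph, atomLabels(nma)),
                                    `[[`, character(1), "canonical"))
  expect_length(extractBonds(make_mol("C"), "C1a"), 0L)
})

test_that("TRIPLET enumeration matches brute force over edge pairs", {
  cpd <- fixture_cpd("alanine")
  trip <- extractTriplets(cpd@graph, atomLabels(cpd))
  expect_length(trip, 6L)
  expect_true("C6a-C1c-N1a" %in% vapply(trip, `[[`, character(1), "canonical"))
  # brute force: every unordered pair of edges sharing an endpoint
  bd <- bondTable(cpd)
  lab <- atomLabels(cpd)
  ref <- character(0)
  for (i in seq_len(nrow(bd) - 1)) {
    for (j in seq.int(i + 1, nrow(bd))) {
      shared <- intersect(c(bd$a[i], bd$b[i]), c(bd$a[j], bd$b[j]))
      if (length(shared) != 1) next
      flanks <- sort(c(lab[setdiff(c(bd$a[i], bd$b[i]), shared)],
                       lab[setdiff(c(bd$a[j], bd$b[j]), shared)]),
                     method = "radix")
      ref <- c(ref, paste(flanks[1], lab[shared], flanks[2], sep = "-"))
    }
  }
  expect_equal(sort(vapply(trip, `[[`, character(1), "canonical")), sort(ref))
  # ethane has no degree-2 center
  eth <- fixture_cpd("ethane")
  expect_length(extractTriplets(eth@graph, atomLabels(eth)), 0L)
})

test_that("VICINITY entries require heavy degree three", {
  ch <- fixture_cpd("cyclohexanol")
  vic <- vapply(extractVicinities(ch@graph, atomLabels(ch)), `[[`,
                character(1), "canonical")
  expect_equal(vic, "C1y(C1x+C1x+O1a)")
  ph <- fixture_cpd("phenol")
  expect_equal(vapply(extractVicinities(ph@graph, atomLabels(ph)), `[[`,
                      character(1), "canonical"),
               "C8y(C8x+C8x+O1a)")
  # the printed sugar-context string appears in ribose
  rib <- fixture_cpd("ribose")
  expect_true("C1y(C1y+C1y+O1a)" %in%
              vapply(extractVicinities(rib@graph, atomLabels(rib)), `[[`,
                     character(1), "canonical"))
  et <- fixture_cpd("ethanol")
  expect_length(extractVicinities(et@graph, atomLabels(et)), 0L)
})

test_that("RING extraction reproduces the printed purine entries", {
  cpd <- fixture_cpd("adenosine")
  s <- substructures(cpd)
  rings <- s$canonical[s$attribute == "RING"]
  expect_true("C8x-N4y(C1y)-C8y-C8y-N5x" %in% rings)           # imidazole ring
  expect_true("C8x-N5x-C8y(N1a)-C8y-C8y-N5x" %in% rings)       # pyrimidine ring
  expect_true("C8x-N4y(C1y)-C8y-N5x-C8x-N5x-C8y(N1a)-C8y-N5x" %in% rings)
  ins <- cpd@substructures
  condensed <- Filter(function(x) x$attribute == "RING" && isTRUE(x$is_condensed), ins)
  expect_length(condensed, 1L)
  expect_equal(condensed[[1]]$backbone_size, 9L)
})

test_that("a benzyl fragment yields the printed phenyl ring string", {
  cpd <- extractSubstructures(kcfCompound(benzyl_mol()))
  s <- substructures(cpd)
  expect_true("C8x-C8x-C8x-C8x-C8x-C8y(C1b)" %in%
              s$canonical[s$attribute == "RING"])
})

test_that("simple rings have no condensed entry", {
  s <- substructures(fixture_cpd("cyclohexane"))
  expect_equal(s$canonical[s$attribute == "RING"],
               "C1x-C1x-C1x-C1x-C1x-C1x")
})

test_that("SKELETON bundles carbon chains with one-shell annotations", {
  s <- substructures(fixture_cpd("leucine_dipeptide"))
  skel <- s$canonical[s$attribute == "SKELETON"]
  expect_true("C1a-C1c(C1a)-C1b-C1c(N1b)-C5a(N1b+O5a)" %in% skel)
  expect_equal(substructures(fixture_cpd("ethane"))$canonical[
    substructures(fixture_cpd("ethane"))$attribute == "SKELETON"], "C1a-C1a")
  # single-carbon components yield no skeleton
  methanol <- extractSubstructures(kcfCompound(
    make_mol(c("C", "O"), rbind(c(1, 2, 1)), id = "methanol")))
  expect_false("SKELETON" %in% substructures(methanol)$attribute)
})

test_that("INORGANIC components render with nested carbon annotations", {
  s <- substructures(fixture_cpd("methyl_phosphate"))
  expect_equal(s$canonical[s$attribute == "INORGANIC"],
               "O1c-P1b(O2b(C1a))(O1c)-O1c")
  s2 <- substructures(fixture_cpd("methanesulfonate"))
  expect_equal(s2$canonical[s2$attribute == "INORGANIC"],
               "O1d-S4a(C1a)(O1d)-O1d")
  expect_false("INORGANIC" %in% substructures(fixture_cpd("ethanol"))$attribute)
})

test_that("extractAll groups the seven attributes with distinct atom sets", {
  cpd <- fixture_cpd("ethanol")
  s <- substructures(cpd)
  tab <- table(s$attribute)
  expect_equal(tab[["ATOM"]], 3L)
  expect_equal(tab[["BOND"]], 2L)
  expect_equal(tab[["TRIPLET"]], 1L)
  expect_equal(tab[["SKELETON"]], 1L)
  expect_false(any(c("VICINITY", "RING", "INORGANIC") %in% names(tab)))

  bz <- substructures(fixture_cpd("benzene"))
  expect_equal(sum(bz$attribute == "ATOM" & bz$canonical == "C8x"), 6L)
  expect_equal(sum(bz$attribute == "BOND"), 6L)
  expect_equal(unique(bz$canonical[bz$attribute == "BOND"]), "C8x-C8x")
  expect_equal(sum(bz$attribute == "RING"), 1L)

  # no canonical string is double-counted for the same atom set
  key <- paste(bz$attribute, bz$canonical,
               vapply(bz$atoms, paste, character(1), collapse = ","))
  expect_false(anyDuplicated(key) > 0)
})

test_that("attribute multisets are invariant under atom permutation", {
  for (nm in c("adenosine", "leucine_dipeptide", "methyl_phosphate", "ribose")) {
    ref <- substr_multiset(fixture_cpd(nm))
    mol <- builtinMolecule(nm)
    for (rep_i in 1:10) {
      set.seed(100 + rep_i)
      perm <- sample(atomCount(mol))
      got <- substr_multiset(extractSubstructures(kcfCompound(permute_mol(mol, perm))))
      expect_equal(got, ref, info = paste(nm, rep_i))
    }
  }
})

test_that("count identities hold on fixtures and random graphs", {
  check_identities <- function(cpd, info) {
    s <- substructures(cpd)
    bd <- bondTable(cpd)
    expect_equal(sum(s$attribute == "ATOM"), atomCount(cpd), info = info)
    expect_equal(sum(s$attribute == "BOND"), nrow(bd), info = info)
    deg <- table(factor(c(bd$a, bd$b), levels = seq_len(atomCount(cpd))))
    expect_equal(sum(s$attribute == "TRIPLET"),
                 sum(choose(as.integer(deg), 2)), info = info)
  }
  for (nm in all_fixture_names) check_identities(fixture_cpd(nm), nm)
  for (seed in 1:25) {
    set.seed(seed)
    mol <- randomMolecule(seed, nAtoms = sample(4:14, 1))
    check_identities(suppressWarnings(extractSubstructures(kcfCompound(mol))),
                     paste("random", seed))
  }
})
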