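# Molfile V2000 / SDF parsing, writing, charge semantics, hydrogen
# suppression and kekulization.

simple_molfile <- function(natoms, nbonds, atom_lines, bond_lines, props = character(0)) {
  paste(c("test", "  prog", "",
          sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", natoms, nbonds),
          atom_lines, bond_lines, props, "M  END"), collapse = "\n")
}

atom_line <- function(el, x = 0, y = 0, charge_code = 0) {
  sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
          x, y, 0, el, charge_code)
}

test_that("ethanol Molfile parses to 3 heavy atoms and 2 bonds", {
  mol <- builtinMolecule("ethanol")
  expect_s4_class(mol, "MolGraph")
  expect_equal(atomCount(mol), 3L)
  expect_equal(bondCount(mol), 2L)
  expect_equal(atomTable(mol)$element, c("C", "C", "O"))
  expect_true(all(is.finite(atomTable(mol)$x)))
})

test_that("M CHG property lines override old-style charge codes", {
  txt <- simple_molfile(2, 1,
    c(atom_line("N", 0, 0, charge_code = 5),  # old code 5 = -1, must be discarded
      atom_line("O", 1, 0)),
    "  1  2  1  0",
    "M  CHG  1   2  -1")
  mol <- readMolfile(txt)
  expect_equal(atomTable(mol)$charge, c(0L, -1L))

  # without M CHG the old code applies
  txt2 <- simple_molfile(2, 1,
    c(atom_line("N", 0, 0, charge_code = 3), atom_line("O", 1, 0)),
    "  1  2  1  0")
  expect_equal(atomTable(readMolfile(txt2))$charge, c(1L, 0L))
})

test_that("parse errors name the offending line", {
  # bond referencing atom 0
  txt <- simple_molfile(2, 1, c(atom_line("C"), atom_line("C")), "  0  2  1  0")
  expect_error(readMolfile(txt), "line 7.*atom 0")
  # unknown element
  txt2 <- simple_molfile(1, 0, atom_line("Qq"), character(0))
  expect_error(readMolfile(txt2), "line 5.*Qq")
  # malformed counts line
  expect_error(readMolfile("t\n\n\nnot a counts line\n"), "line 4")
})

test_that("V3000 input is rejected with a clear message", {
  txt <- paste(c("t", "", "", "  0  0  0     0  0            999 V3000"), collapse = "\n")
  expect_error(readMolfile(txt), "V3000")
})

test_that("explicit hydrogens are suppressed and recorded as implicit counts", {
  # methanol drawn with all hydrogens explicit
  txt <- simple_molfile(6, 5,
    c(atom_line("C"), atom_line("O", 1), atom_line("H", -1), atom_line("H", 0, 1),
      atom_line("H", 0, -1), atom_line("H", 2)),
    c("  1  2  1  0", "  1  3  1  0", "  1  4  1  0", "  1  5  1  0", "  2  6  1  0"))
  mol <- readMolfile(txt)
  expect_equal(atomCount(mol), 2L)
  expect_equal(bondCount(mol), 1L)
  expect_equal(atomTable(mol)$hcount, c(3L, 1L))
  expect_equal(atomTable(mol)$element, c("C", "O"))
})

test_that("aromatic (type 4) bonds are kekulized to alternating orders", {
  bonds <- sprintf("%3d%3d  4  0", 1:6, c(2:6, 1))
  txt <- simple_molfile(6, 6, replicate(6, atom_line("C")), bonds)
  mol <- readMolfile(txt)
  expect_setequal(unique(bondTable(mol)$order), c(1L, 2L))
  expect_equal(sum(bondTable(mol)$order == 2L), 3L)
  # every carbon has exactly one double bond
  dbl <- bondTable(mol)[bondTable(mol)$order == 2L, ]
  expect_setequal(c(dbl$a, dbl$b), 1:6)
})

test_that("unkekulizable aromatic systems are an error", {
  # 5-cycle of all-carbon aromatic bonds cannot be assigned alternating orders
  bonds <- sprintf("%3d%3d  4  0", 1:5, c(2:5, 1))
  txt <- simple_molfile(5, 5, replicate(5, atom_line("C")), bonds)
  expect_error(readMolfile(txt), "kekulize")
})

test_that("read/write round trip preserves every fixture graph", {
  for (nm in all_fixture_names) {
    mol <- builtinMolecule(nm)
    back <- readMolfile(writeMolfile(mol))
    expect_equal(atomTable(back)$element, atomTable(mol)$element, info = nm)
    expect_equal(atomTable(back)$charge, atomTable(mol)$charge, info = nm)
    expect_equal(bondTable(back)[, c("a", "b", "order")],
                 bondTable(mol)[, c("a", "b", "order")], info = nm)
    expect_equal(atomTable(back)$x, atomTable(mol)$x, tolerance = 1e-4, info = nm)
  }
})

test_that("charged atoms round trip through M CHG lines", {
  mol <- make_mol(c("N", "C"), rbind(c(1, 2, 1)), charges = c(1L, 0L))
  txt <- writeMolfile(mol)
  expect_match(txt, "M  CHG  1   1   1")
  expect_equal(atomTable(readMolfile(txt))$charge, c(1L, 0L))
})

test_that("graphs beyond the V2000 atom limit are rejected on write", {
  big <- make_mol(rep("C", 1000),
                  cbind(seq_len(999), seq_len(999) + 1L, 1L))
  expect_error(writeMolfile(big), "999 atoms")
})

test_that("SDF streams split on $$$$ with lenient and strict modes", {
  two <- paste0(writeMolfile(builtinMolecule("ethanol")), "$$$$\n",
                writeMolfile(builtinMolecule("ethane")), "$$$$\n")
  mols <- readSDF(two)
  expect_length(mols, 2L)
  expect_equal(vapply(mols, atomCount, integer(1)), c(3L, 2L))

  corrupt <- paste0(writeMolfile(builtinMolecule("ethanol")), "$$$$\n",
                    "garbage\nrecord\n$$$$\n")
  expect_warning(lenient <- readSDF(corrupt, strict = FALSE), "record 2")
  expect_length(lenient, 1L)
  expect_error(readSDF(corrupt, strict = TRUE), "record 2")

  expect_length(readSDF(""), 0L)
})

test_that("parsed fixtures agree with an independent SDF reader", {
  skip_if_not_installed("ChemmineR")
  path <- tempfile(fileext = ".sdf")
  writeSDF(lapply(all_fixture_names, builtinMolecule), path)
  sdf <- ChemmineR::read.SDFset(path)
  for (k in seq_along(all_fixture_names)) {
    mol <- builtinMolecule(all_fixture_names[k])
    ab <- ChemmineR::atomblock(sdf[[k]])
    bb <- ChemmineR::bondblock(sdf[[k]])
    expect_equal(atomCount(mol), nrow(ab), info = all_fixture_names[k])
    expect_equal(bondCount(mol), nrow(bb), info = all_fixture_names[k])
  }
})
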