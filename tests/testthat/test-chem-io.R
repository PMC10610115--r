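test_that("SMILES list reader parses valid entries and skips bad ones", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines("CCO eth1", f)
  lib <- readStructures(f, "smiles")
  expect_equal(nMolecules(lib), 1L)
  expect_equal(nrow(lib[[1]]@atoms), 3L)
  expect_equal(lib[[1]]@id, "eth1")

  f2 <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO", "not_a_smiles"), f2)
  expect_message(lib2 <- readStructures(f2, "smiles"), "skipped")
  expect_equal(nMolecules(lib2), 1L)
  expect_equal(length(lib2@skipped), 1L)

  expect_error(readStructures(withr::local_tempfile(), "smiles"), "not found")
})

test_that("SDF reader attaches conformers only for genuine 3D entries", {
  f <- withr::local_tempfile(fileext = ".sdf")
  writeLines(twoMolSDFText(), f)
  lib <- readStructures(f, "sdf")
  expect_equal(nMolecules(lib), 2L)
  expect_equal(nrow(lib[[1]]@atoms), 3L)  # independent atom count
  expect_equal(nrow(lib[[2]]@atoms), 3L)
  expect_null(lib[[1]]@conformer)
  expect_true(is.matrix(lib[[2]]@conformer))
})

test_that("CSV reader requires a smiles column and keeps ids", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(id = c("a", "b"), smiles = c("CCO", "c1ccccc1")), f,
            row.names = FALSE)
  lib <- readStructures(f, "csv")
  expect_equal(molIds(lib), c("a", "b"))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(x = 1), f2, row.names = FALSE)
  expect_error(readStructures(f2, "csv"), "smiles")
})

test_that("standardization keeps the larger organic fragment and rejects inorganics", {
  m <- standardizeMolecule(moleculeFromSmiles("CC(=O)[O-].[Na+]", "ace"))
  expect_equal(nrow(m@atoms), 4L)  # acetate: 4 heavy atoms vs 1 for Na+
  expect_false("Na" %in% m@atoms$element)

  m2 <- moleculeFromSmiles("CCO", "eth")
  expect_equal(standardizeMolecule(m2)@smiles, m2@smiles)

  expect_error(standardizeMolecule(moleculeFromSmiles("[Na+].[Cl-]", "salt")),
               "organic")
})

test_that("parse-standardize-serialize round trip is idempotent", {
  for (smi in c("CCO", cpd6Smiles, "CC(=O)[O-].[Na+]", "c1cc[nH]c1")) {
    m1 <- standardizeMolecule(moleculeFromSmiles(smi, "x"))
    m2 <- standardizeMolecule(moleculeFromSmiles(m1@smiles, "x"))
    expect_equal(m2@smiles, m1@smiles, info = smi)
    expect_equal(nrow(m2@atoms), nrow(m1@atoms), info = smi)
    expect_equal(sort(m2@bonds$order), sort(m1@bonds$order), info = smi)
  }
})

test_that("molecular weight is additive over disconnected fragments", {
  mw <- function(smi) computeDescriptors(moleculeFromSmiles(smi, "x"))@mw
  expect_equal(mw("CCO.CC(=O)O"), mw("CCO") + mw("CC(=O)O"), tolerance = 1e-9)
})

test_that("compound 6 reproduces its published descriptor row exactly", {
  d <- computeDescriptors(cpd6Record())
  expect_equal(round(d@mw, 1), 399.5)
  expect_equal(d@heavyAtoms, 29L)
  expect_equal(d@hbd, 1L)
  expect_equal(d@hba, 4L)
  expect_equal(d@rotBonds, 5L)
  expect_equal(round(d@tpsa, 1), 83.1)
})

test_that("removing the tolyl methyl lowers the heavy-atom count by exactly one", {
  noMethyl <- moleculeFromSmiles(
    "CCc1nc(-c2ccccc2)c(-c2ccnc(NC(=O)c3ccccc3)c2)s1", "cpd6des")
  expect_equal(computeDescriptors(noMethyl)@heavyAtoms,
               computeDescriptors(cpd6Record())@heavyAtoms - 1L)
})

test_that("known fragment TPSA values and degenerate molecules are exact", {
  d <- computeDescriptors(moleculeFromSmiles("CCO", "eth"))
  expect_equal(d@tpsa, 20.23, tolerance = 1e-9)  # single hydroxyl contribution
  expect_equal(d@hbd, 1L)
  dm <- computeDescriptors(moleculeFromSmiles("C", "methane"))
  expect_equal(dm@heavyAtoms, 1L)
  expect_equal(dm@hbd + dm@hba + dm@rotBonds, 0L)
  expect_equal(dm@tpsa, 0)
  # disabling the sulfur contribution must remove the aromatic-S term
  dS <- computeDescriptors(cpd6Record(), tpsaSP = FALSE)
  expect_equal(dS@tpsa, computeDescriptors(cpd6Record())@tpsa - 28.24,
               tolerance = 1e-9)
})

test_that("descriptors are invariant to SMILES atom-order permutation", {
  variants <- c("c1ccccc1CCO", "OCCc1ccccc1", "C(c1ccccc1)CO")
  ds <- lapply(variants, function(s)
    computeDescriptors(moleculeFromSmiles(s, "v")))
  for (d in ds[-1]) {
    expect_equal(d@tpsa, ds[[1]]@tpsa)
    expect_equal(d@mw, ds[[1]]@mw)
    expect_equal(c(d@hbd, d@hba, d@rotBonds, d@heavyAtoms),
                 c(ds[[1]]@hbd, ds[[1]]@hba, ds[[1]]@rotBonds,
                   ds[[1]]@heavyAtoms))
  }
})

test_that("descriptor tables keep one row per molecule and flag failures", {
  lib <- methods::new("MoleculeLibrary", records = list(
    moleculeFromSmiles("CCO", "a"), cpd6Record()))
  tab <- descriptorTable(lib)
  expect_equal(nrow(tab), 2L)
  expect_equal(names(tab)[1:7],
               c("id", "mw", "heavy_atoms", "hbd", "hba", "rot_bonds", "tpsa"))
  d6 <- computeDescriptors(cpd6Record())
  expect_equal(tab$tpsa[2], d6@tpsa)
  expect_equal(tab$mw[2], d6@mw)
  # CSV write/read round trip at report precision
  f <- withr::local_tempfile(fileext = ".csv")
  writeDescriptorCSV(tab, f)
  back <- read.csv(f)
  expect_equal(back$mw, round(tab$mw, 1))
})
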