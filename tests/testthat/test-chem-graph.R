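test_that("parse_structure builds correct graphs for printed molecules", {
  m <- parse_structure("C", "smiles")
  expect_equal(m$n_atoms, 1L)
  expect_equal(m$n_bonds, 0L)
  expect_equal(m$atoms$nH, 4L)

  b <- parse_structure("CCCC", "smiles")
  expect_equal(b$n_atoms, 4L)
  expect_equal(b$n_bonds, 3L)
  expect_true(all(b$bonds$order == 1L))

  bz <- parse_structure("c1ccccc1", "smiles")
  expect_equal(bz$n_atoms, 6L)
  expect_equal(sum(bz$atoms$aromatic), 6L)
  expect_equal(sum(bz$bonds$aromatic), 6L)
  expect_equal(length(bz$rings), 1L)
})

test_that("aromatic perception follows the 4n+2 rule on heteroaromatics", {
  expect_equal(sum(parse_structure("c1ccncc1", "smiles")$atoms$aromatic), 6L)
  expect_equal(sum(parse_structure("c1ccoc1", "smiles")$atoms$aromatic), 5L)
  expect_equal(sum(parse_structure("c1cc[nH]c1", "smiles")$atoms$aromatic), 5L)
  expect_equal(sum(parse_structure("C1CCCCC1", "smiles")$atoms$aromatic), 0L)
  # quinone carbonyl carbons break the ring current
  expect_equal(sum(parse_structure("O=C1C=CC(=O)C=C1", "smiles")$atoms$aromatic), 0L)
  # naphthalene: fused pair, all ten atoms aromatic
  expect_equal(sum(parse_structure("c1ccc2ccccc2c1", "smiles")$atoms$aromatic), 10L)
})

test_that("formats beyond SMILES parse to the same graph", {
  sm <- parse_structure("CCO", "smiles")
  inchi <- parse_structure("InChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3", "inchi")
  expect_equal(inchi$n_atoms, sm$n_atoms)
  expect_equal(sort(inchi$atoms$element), sort(sm$atoms$element))
  expect_equal(sum(inchi$atoms$nH), sum(sm$atoms$nH))

  sdf <- ChemmineOB::convertFormat("SMI", "SDF", "CCO\nCCCC\n")
  mols <- parse_structures(sdf, "sdf")
  expect_length(mols, 2L)
  expect_equal(mols[[2]]$n_atoms, 4L)
  expect_equal(parse_structure(sdf, "sdf")$n_atoms, 3L)

  expect_error(parse_structure("", "smiles"), "empty")
  expect_error(parse_structure("not-a-smiles((", "smiles"), "cannot parse")
})

test_that("standardization strips salts, neutralizes and is idempotent", {
  m <- parse_structure("CC(=O)[O-].[Na+]", "smiles")
  s <- standardize_structure(m)
  expect_equal(s$n_atoms, 4L)                 # acetic acid skeleton
  expect_true(all(s$atoms$charge == 0L))
  expect_true("Na" %in% m$atoms$element && !"Na" %in% s$atoms$element)

  # already-standard molecule is a fixed point
  e <- parse_structure("CCO", "smiles")
  se <- standardize_structure(e)
  expect_equal(se$atoms, e$atoms)
  expect_equal(se$bonds, e$bonds)

  # idempotence over the fixture set
  for (m in fixture_mols()) {
    s1 <- standardize_structure(m)
    s2 <- standardize_structure(s1)
    expect_equal(s1$atoms, s2$atoms)
    expect_equal(s1$bonds, s2$bonds)
  }
})

test_that("standardization options toggle independently", {
  m <- parse_structure("CC(=O)[O-].[Na+]", "smiles")
  keep_all <- standardize_structure(
    m, standardization_options(largest_fragment = FALSE, neutralize = FALSE))
  expect_equal(keep_all$n_atoms, 5L)
  expect_equal(sum(keep_all$atoms$charge), 0L)  # +1 and -1 retained
  frag_only <- standardize_structure(
    m, standardization_options(neutralize = FALSE))
  expect_equal(frag_only$n_atoms, 4L)
  expect_equal(sum(frag_only$atoms$charge), -1L)
  flags <- attr(frag_only, "validation")
  expect_true(any(grepl("net formal charge", flags)))
})
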