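test_that("the registry exposes 19 families at their pinned lengths", {
  reg <- list_fingerprint_families()
  expect_equal(nrow(reg), 19L)
  expect_equal(reg$length[reg$name == "maccs"], 166L)
  expect_equal(reg$length[reg$name == "pubchem"], 881L)
  expect_equal(reg$length[reg$name == "estate_fp"], 79L)
  expect_equal(reg$length[reg$name == "fp3"], 210L)
  expect_equal(reg$length[reg$name == "fp4"], 307L)
  expect_equal(reg$length[reg$name == "ghosecrippen"], 110L)
  expect_equal(reg$length[reg$name == "pharm2p"], 135L)
  expect_equal(reg$length[reg$name == "pharm3p"], 2135L)
  expect_true(all(reg$length[grepl("^(ecfp|fcfp|morgan|fp2)", reg$name)] == 1024L))
  expect_true(all(reg$length[reg$name %in% c("daylight", "atompairs", "torsion")] == 2048L))
  expect_identical(reg, list_fingerprint_families())  # stable across calls
})

test_that("every family computes at its registered length and is deterministic", {
  et <- fixture_mols()$ethanol
  reg <- list_fingerprint_families()
  for (i in seq_len(nrow(reg))) {
    fp <- fingerprint(et, reg$name[i])
    expect_length(fp, reg$length[i])
    expect_true(all(fp >= 0L))
    if (reg$kind[i] == "bit") expect_true(all(fp <= 1L))
    expect_identical(as.integer(fingerprint(et, reg$name[i])), as.integer(fp))
  }
  expect_error(fingerprint(et, "nope"), "available")
})

test_that("substructure-key bits are monotone from ethane to n-butane", {
  e2 <- fixture_mols()$ethane
  b4 <- fixture_mols()$butane
  for (fam in c("maccs", "fp4", "pubchem")) {
    fe <- fingerprint(e2, fam)
    fb <- fingerprint(b4, fam)
    expect_true(all(fb[fe > 0] > 0),
                label = paste(fam, "bits set for ethane also set for butane"))
  }
})

test_that("methane maps to exactly one E-state atom-type bin", {
  fp <- fingerprint(fixture_mols()$methane, "estate_fp")
  expect_equal(sum(fp > 0), 1L)
  expect_equal(sum(fp), 1L)
})

test_that("fingerprints separate structurally distinct molecules", {
  et <- fixture_mols()$ethanol
  bz <- fixture_mols()$benzene
  for (fam in c("maccs", "ecfp4", "daylight", "atompairs"))
    expect_false(identical(as.integer(fingerprint(et, fam)),
                           as.integer(fingerprint(bz, fam))))
  # and respellings of one molecule collide
  a <- parse_structure("OCC", "smiles")
  for (fam in c("maccs", "ecfp4", "pubchem"))
    expect_identical(as.integer(fingerprint(a, fam)),
                     as.integer(fingerprint(et, fam)))
})

test_that("fingerprint dimensions hold across the whole fixture set", {
  reg <- list_fingerprint_families()
  fams <- c("maccs", "estate_fp", "ecfp4", "pharm2p")
  for (m in fixture_mols())
    for (fam in fams)
      expect_length(fingerprint(m, fam), reg$length[reg$name == fam])
})
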