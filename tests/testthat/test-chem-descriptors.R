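test_that("descriptor groups have their fixed dimensions on every fixture", {
  sizes <- chem_group_sizes()
  expect_equal(sum(sizes), 775L)
  for (m in fixture_mols())
    for (g in names(sizes))
      expect_length(descriptor_group(m, g), sizes[[g]])
  expect_error(descriptor_group(fixture_mols()[[1]], "nope"), "unknown")
})

test_that("all_descriptors yields 775 uniquely named finite values", {
  for (nm in c("ethanol", "benzene", "aspirin", "methane")) {
    v <- all_descriptors(fixture_mols()[[nm]])
    expect_length(v, 775L)
    expect_false(anyDuplicated(names(v)) > 0)
    expect_true(all(is.finite(v)))
  }
  # determinism
  v1 <- all_descriptors(fixture_mols()$ethanol)
  v2 <- all_descriptors(fixture_mols()$ethanol)
  expect_identical(unclass(v1), unclass(v2))
})

test_that("descriptors are invariant under SMILES respelling", {
  pairs <- list(c("CCO", "OCC"), c("CC(C)C", "C(C)(C)C"),
                c("c1ccccc1C", "Cc1ccccc1"), c("O=C(C)O", "CC(O)=O"))
  for (p in pairs) {
    a <- all_descriptors(parse_structure(p[1], "smiles"))
    b <- all_descriptors(parse_structure(p[2], "smiles"))
    expect_equal(unclass(a), unclass(b), tolerance = 1e-9)
  }
})

test_that("topological descriptors match brute-force graph oracles", {
  # n-butane: Wiener = 1+2+3+1+2+1 = 10, kappa1 = 4*9/9 = 4
  bu <- fixture_mols()$butane
  expect_equal(unname(descriptor_group(bu, "topology")["topo.W"]), 10)
  expect_equal(unname(descriptor_group(bu, "kappa")["kappa.kappa1"]), 4.0)

  for (nm in c("ethanol", "isobutane", "benzene", "acetic_acid", "furan")) {
    m <- fixture_mols()[[nm]]
    d <- bfs_distances(m)            # independent BFS oracle
    W <- sum(d[upper.tri(d)])
    expect_equal(unname(descriptor_group(m, "topology")["topo.W"]), W)
    deg <- m$atoms$degree
    expect_equal(unname(descriptor_group(m, "topology")["topo.ZM1"]),
                 sum(deg^2))
    # chi0 and chi1 by direct formula
    conn <- descriptor_group(m, "connectivity")
    expect_equal(unname(conn["conn.chi0"]), sum(1 / sqrt(deg)),
                 tolerance = 1e-10)
    chi1 <- sum(1 / sqrt(deg[m$bonds$a1] * deg[m$bonds$a2]))
    expect_equal(unname(conn["conn.chi1"]), chi1, tolerance = 1e-10)
    # kappa1-3 by direct formula
    A <- m$n_atoms
    paths2 <- sum(vapply(seq_len(A), function(i) choose(sum(d[i, ] == 1), 2),
                         numeric(1)))
    kap <- descriptor_group(m, "kappa")
    if (m$n_bonds > 0)
      expect_equal(unname(kap["kappa.kappa1"]), A * (A - 1)^2 / m$n_bonds^2,
                   tolerance = 1e-10)
    if (paths2 > 0)
      expect_equal(unname(kap["kappa.kappa2"]), (A - 1) * (A - 2)^2 / paths2^2,
                   tolerance = 1e-10)
  }
})

test_that("autocorrelation groups match a double-loop oracle over atom pairs", {
  for (nm in c("ethanol", "aspirin", "pyridine")) {
    m <- fixture_mols()[[nm]]
    d <- bfs_distances(m)
    # oracle for the mass weighting (first 8 entries of each flavour)
    p <- biodesc:::element_prop(m$atoms$element, "mass", 12.011) / 12.011
    mb <- descriptor_group(m, "autocorrelation_mb")
    mo <- descriptor_group(m, "autocorrelation_moran")
    ge <- descriptor_group(m, "autocorrelation_geary")
    n <- m$n_atoms
    for (lag in 1:8) {
      acc <- 0; cnt <- 0; msum <- 0; gsum <- 0
      for (i in seq_len(n - 1)) for (j in (i + 1):n) if (d[i, j] == lag) {
        acc <- acc + p[i] * p[j]
        msum <- msum + (p[i] - mean(p)) * (p[j] - mean(p))
        gsum <- gsum + (p[i] - p[j])^2
        cnt <- cnt + 1
      }
      expect_equal(unname(mb[lag]), acc, tolerance = 1e-10)
      ss <- sum((p - mean(p))^2)
      moran_exp <- if (cnt == 0 || ss == 0) 0 else (msum / cnt) / (ss / n)
      geary_exp <- if (cnt == 0 || ss == 0) 0 else
        (gsum / (2 * cnt)) / (ss / (n - 1))
      expect_equal(unname(mo[lag]), moran_exp, tolerance = 1e-10)
      expect_equal(unname(ge[lag]), geary_exp, tolerance = 1e-10)
    }
  }
})

test_that("degenerate graphs give finite zero-filled descriptors", {
  me <- fixture_mols()$methane
  v <- all_descriptors(me)
  expect_true(all(is.finite(v)))
  expect_equal(unname(v["topo.W"]), 0)
  expect_equal(unname(v["conn.chi1"]), 0)
})

test_that("charge descriptors are electronegativity-coherent", {
  v <- descriptor_group(fixture_mols()$ethanol, "charge")
  # oxygen carries the most negative charge in ethanol
  expect_lt(unname(v["charge.QOmin"]), 0)
  expect_gt(unname(v["charge.QHmax"]), 0)
  expect_equal(unname(v["charge.Qmin"]), unname(v["charge.QOmin"]))
  # charges approximately sum to the net formal charge (0)
  g <- gasteiger_charges(fixture_mols()$ethanol)
  expect_equal(sum(g$all), 0, tolerance = 1e-6)
})

test_that("molecular property block is chemically plausible", {
  v_oct <- descriptor_group(parse_structure("CCCCCCCC", "smiles"), "property")
  v_gly <- descriptor_group(fixture_mols()$glycine, "property")
  expect_gt(unname(v_oct["prop.logp"]), unname(v_gly["prop.logp"]))
  expect_equal(unname(v_oct["prop.tpsa"]), 0)
  expect_gt(unname(v_gly["prop.tpsa"]), 50)
  expect_equal(unname(v_gly["prop.logp2"]), unname(v_gly["prop.logp"])^2)
})
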