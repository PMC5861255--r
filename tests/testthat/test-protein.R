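test_that("peptide composition matches direct window counts and sums to 1", {
  v <- peptide_composition("MM", k = 1)
  expect_equal(unname(v["M"]), 1.0)
  expect_equal(sum(v), 1.0)
  expect_length(v, 20L)

  v2 <- peptide_composition("MKM", k = 2)
  expect_equal(unname(v2["MK"]), 0.5)
  expect_equal(unname(v2["KM"]), 0.5)
  expect_equal(sum(v2 != 0), 2L)
  expect_length(v2, 400L)

  v3 <- peptide_composition(random_sequences("protein", 1, 40, 5), k = 3)
  expect_length(v3, 8000L)
  expect_equal(sum(v3), 1.0, tolerance = 1e-12)

  for (s in random_sequences("protein", 5, 30, 9))
    for (k in 1:3)
      expect_equal(sum(peptide_composition(s, k)), 1.0, tolerance = 1e-12)

  expect_error(peptide_composition("MK", k = 3), "shorter")
})

test_that("autocorrelation equals a brute-force loop oracle on short sequences", {
  props <- aa_properties("autocorrelation")[1]
  P_of <- function(s) unname(props[[1]][strsplit(s, "")[[1]]])
  for (s in random_sequences("protein", 5, 35, 21)) {
    P <- P_of(s); L <- length(P)
    got <- list(
      mb = autocorrelation(s, "moreau_broto", props, maxlag = 3),
      moran = autocorrelation(s, "moran", props, maxlag = 3),
      geary = autocorrelation(s, "geary", props, maxlag = 3))
    for (d in 1:3) {
      acc <- 0; for (i in 1:(L - d)) acc <- acc + P[i] * P[i + d]
      expect_equal(unname(got$mb[d]), acc / (L - d), tolerance = 1e-10)
      num <- 0; for (i in 1:(L - d)) num <- num + (P[i] - mean(P)) * (P[i + d] - mean(P))
      moran_exp <- (num / (L - d)) / (sum((P - mean(P))^2) / L)
      expect_equal(unname(got$moran[d]), moran_exp, tolerance = 1e-10)
      sq <- 0; for (i in 1:(L - d)) sq <- sq + (P[i] - P[i + d])^2
      geary_exp <- (sq / (2 * (L - d))) / (sum((P - mean(P))^2) / (L - 1))
      expect_equal(unname(got$geary[d]), geary_exp, tolerance = 1e-10)
    }
  }
})

test_that("autocorrelation defaults give 240 values; homopolymers degenerate to 0", {
  s <- random_sequences("protein", 1, 60, 3)
  for (kind in c("moreau_broto", "moran", "geary"))
    expect_length(autocorrelation(s, kind), 240L)
  homo <- strrep("A", 40)
  expect_true(all(autocorrelation(homo, "moran", maxlag = 5) == 0))
  expect_true(all(autocorrelation(homo, "geary", maxlag = 5) == 0))
  expect_error(autocorrelation("MKVL", maxlag = 10), "maxlag")
})

test_that("ctd has the 21/21/105 layout with coherent blocks", {
  s <- random_sequences("protein", 1, 50, 13)
  v <- ctd(s)
  expect_length(v, 147L)
  comp <- v[startsWith(names(v), "ctd.comp.")]
  trans <- v[startsWith(names(v), "ctd.trans.")]
  dist <- v[startsWith(names(v), "ctd.dist.")]
  expect_length(comp, 21L); expect_length(trans, 21L); expect_length(dist, 105L)
  # per-attribute composition sums to 1
  for (g in ctd_groupings()) {
    blk <- comp[grep(paste0("\\.", g$attribute, "\\."), names(comp))]
    expect_equal(sum(blk), 1.0, tolerance = 1e-12)
  }
  expect_true(all(dist >= 0 & dist <= 100))

  # homopolymer: class containing A has composition 1, all transitions 0
  vh <- ctd(strrep("A", 30))
  expect_true(all(vh[startsWith(names(vh), "ctd.trans.")] == 0))
  expect_equal(unname(vh["ctd.comp.charge.c2"]), 1.0)  # A is in the neutral class

  # two-residue sequence crossing one class boundary: transition = 1
  # (A and R are in different hydrophobicity classes)
  var <- ctd("AR")
  expect_equal(unname(var["ctd.trans.hydrophobicity.c12"]), 1.0)
})

test_that("conjoint triads count class windows", {
  expect_length(conjoint_triad("AAA"), 343L)
  v <- conjoint_triad("AAA")
  expect_equal(unname(v["triad.1.1.1"]), 1)
  expect_equal(sum(v), 1)
  v4 <- conjoint_triad("AAAA")
  expect_equal(unname(v4["triad.1.1.1"]), 2)
  # total windows = L - 2 for any sequence
  s <- random_sequences("protein", 1, 37, 4)
  expect_equal(sum(conjoint_triad(s)), 35)
  expect_error(conjoint_triad("MK"), "length")
})

test_that("socn equals the brute-force coupling sum; homopolymer gives 0", {
  mats <- aa_distance_matrices()[1]
  for (s in random_sequences("protein", 5, 10, 31)) {
    v <- socn(s, mats, maxlag = 2)
    chars <- strsplit(s, "")[[1]]
    m <- mats[[1]]
    for (d in 1:2) {
      tau <- 0
      for (i in 1:(10 - d)) tau <- tau + m[chars[i], chars[i + d]]^2
      expect_equal(unname(v[d]), tau, tolerance = 1e-10)
    }
  }
  expect_length(socn(random_sequences("protein", 1, 40, 2)), 60L)
  expect_true(all(socn(strrep("K", 35)) == 0))
})

test_that("qso blocks sum to 1 per matrix; homopolymer collapses to frequency", {
  s <- random_sequences("protein", 1, 45, 17)
  v <- qso(s)
  expect_length(v, 100L)
  for (mname in names(aa_distance_matrices())) {
    blk <- v[grep(paste0("^qso\\.", mname, "\\."), names(v))]
    expect_length(blk, 50L)
    expect_equal(sum(blk), 1.0, tolerance = 1e-12)
    expect_true(all(blk >= 0))
  }
  vh <- qso(strrep("A", 35))
  expect_equal(unname(vh["qso.grantham.A"]), 1.0)
  expect_true(all(vh[grep("tau", names(vh))] == 0))
})

test_that("pseaac normalizes to 1 with nonnegative entries", {
  s <- random_sequences("protein", 1, 45, 23)
  v <- pseaac(s)
  expect_length(v, 50L)
  expect_equal(sum(v), 1.0, tolerance = 1e-12)
  expect_true(all(v >= 0))
  # homopolymer: all correlation factors vanish, the residue owns the mass
  vh <- pseaac(strrep("G", 40), lambda = 5)
  expect_true(all(vh[grep("theta", names(vh))] == 0))
  expect_equal(unname(vh["pseaac.G"]), 1.0)
  expect_error(pseaac("MKVL", lambda = 10), "lambda")
})

test_that("apseaac has dimension 20 + 2*lambda and sums to 1", {
  s <- random_sequences("protein", 1, 45, 29)
  expect_length(apseaac(s), 50L)              # default lambda = 15
  expect_length(apseaac(s, lambda = 30), 80L) # 20 + 2*30
  expect_equal(sum(apseaac(s)), 1.0, tolerance = 1e-12)
})

test_that("protein_all concatenates all families with unique names (9890)", {
  s <- random_sequences("protein", 1, 60, 37)
  v <- protein_all(s)
  expect_length(v, 20L + 400L + 8000L + 3L * 240L + 147L + 343L + 60L +
                  100L + 50L + 50L)
  expect_false(anyDuplicated(names(v)) > 0)
  expect_true(all(is.finite(v)))
  expect_identical(unclass(protein_all(s)), unclass(v))  # deterministic
  expect_error(protein_all(strrep("A", 25)), "length > 30")
})

test_that("feature dimensions are content-independent across random sequences", {
  lens <- vapply(random_sequences("protein", 20, 40, 41), function(s)
    c(length(pseaac(s, lambda = 5)), length(ctd(s)), length(qso(s, maxlag = 4))),
    numeric(3L))
  expect_true(all(lens[1, ] == 25L))
  expect_true(all(lens[2, ] == 147L))
  expect_true(all(lens[3, ] == 48L))
})
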