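test_that("kmer composition counts sliding windows", {
  v <- kmer_composition("AA", k = 2)
  expect_equal(unname(v["kmer2.AA"]), 1.0)
  expect_equal(sum(v != 0), 1L)
  expect_length(v, 16L)

  v1 <- kmer_composition("ACGT", k = 1, normalize = FALSE)
  expect_equal(unname(v1), rep(1, 4))

  s <- random_sequences("dna", 1, 60, 7)
  expect_equal(sum(kmer_composition(s, 3)), 1.0, tolerance = 1e-12)
  expect_equal(sum(kmer_composition(s, 3, normalize = FALSE)), 58)
  expect_error(kmer_composition("AC", k = 3), "shorter")
})

test_that("canonical kmer vectors are reverse-complement invariant", {
  revcomp_str <- function(s)
    paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
  expect_length(kmer_composition("ACGTAC", 2, canonical = TRUE), 10L)
  for (s in random_sequences("dna", 100, 30, 19)) {
    a <- kmer_composition(s, 2, canonical = TRUE)
    b <- kmer_composition(revcomp_str(s), 2, canonical = TRUE)
    expect_equal(unclass(a), unclass(b), tolerance = 1e-12)
  }
})

test_that("covariance matches a brute-force positional loop", {
  props <- oligo_properties(2L)[, 1:2]
  for (s in random_sequences("dna", 5, 20, 43)) {
    va <- covariance(s, 2, "auto", props, maxlag = 2)
    vc <- covariance(s, 2, "cross", props, maxlag = 2)
    words <- substring(s, 1:19, 2:20)
    prof <- props[words, ]
    for (u in 1:2) for (d in 1:2) {
      pm <- mean(prof[, u]); n <- 19
      acc <- 0
      for (i in 1:(n - d)) acc <- acc + (prof[i, u] - pm) * (prof[i + d, u] - pm)
      expect_equal(unname(va[(u - 1) * 2 + d]), acc / (n - d), tolerance = 1e-10)
    }
    idx <- 0
    for (u1 in 1:2) for (u2 in 1:2) {
      if (u1 == u2) next
      for (d in 1:2) {
        idx <- idx + 1
        m1 <- mean(prof[, u1]); m2 <- mean(prof[, u2]); n <- 19
        acc <- 0
        for (i in 1:(n - d)) acc <- acc + (prof[i, u1] - m1) * (prof[i + d, u2] - m2)
        expect_equal(unname(vc[idx]), acc / (n - d), tolerance = 1e-10)
      }
    }
  }
})

test_that("covariance defaults reproduce the dimension table; homopolymer gives 0", {
  s <- random_sequences("dna", 1, 60, 3)
  expect_length(covariance(s, 2, "auto"), 76L)
  expect_length(covariance(s, 2, "cross"), 2812L)
  expect_length(covariance(s, 2, "autocross"), 2888L)
  expect_length(covariance(s, 3, "auto"), 24L)
  expect_length(covariance(s, 3, "cross"), 264L)
  expect_length(covariance(s, 3, "autocross"), 288L)
  expect_true(all(covariance(strrep("A", 20), 2, "auto") == 0))
  expect_error(covariance(s, 2, "cross", oligo_properties(2)[, 1, drop = FALSE]),
               "2 properties")
  expect_error(covariance("ACGT", 2, "auto", maxlag = 5), "too short")
})

test_that("pseudo nucleotide composition normalizes to 1", {
  s <- random_sequences("dna", 1, 50, 11)
  v <- pse_composition(s, 2, lambda = 2)
  expect_length(v, 18L)
  expect_equal(sum(v), 1.0, tolerance = 1e-12)
  expect_true(all(v >= 0))
  expect_length(pse_composition(s, 3, lambda = 2), 66L)
  expect_length(pse_composition(s, 2, correlation = "series"), 92L)
  expect_length(pse_composition(s, 3, correlation = "series"), 88L)

  # homopolymer: zero correlation factors, frequency block owns the mass
  vh <- pse_composition(strrep("G", 30), 2, lambda = 2)
  expect_true(all(vh[grep("theta", names(vh))] == 0))
  expect_equal(unname(vh["psednc.GG"]), 1.0)
  expect_error(pse_composition("ACG", 2, lambda = 5), "too short")
})

test_that("parallel pseudo composition is invariant to property column order", {
  s <- random_sequences("dna", 1, 40, 13)
  p <- oligo_properties(2L)
  a <- pse_composition(s, 2, props = p)
  b <- pse_composition(s, 2, props = p[, rev(seq_len(ncol(p)))])
  expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-12)
})

test_that("dna_all concatenates every family with unique names (> 6000)", {
  s <- random_sequences("dna", 1, 80, 17)
  v <- dna_all(s)
  expect_gt(length(v), 6000L)
  expect_equal(length(v), 16L + 10L + 76L + 2812L + 2888L + 24L + 264L +
                 288L + 18L + 66L + 92L + 88L)
  expect_false(anyDuplicated(names(v)) > 0)
  expect_identical(unclass(dna_all(s)), unclass(v))
  expect_error(dna_all("ACGTACG"), "length >= 10")
})

test_that("oligo property tables are standardized over the 4^k oligos", {
  for (k in 2:3) {
    p <- oligo_properties(k)
    expect_equal(nrow(p), 4^k)
    expect_true(all(abs(colMeans(p)) < 1e-9))
    expect_true(all(abs(apply(p, 2, function(v) sqrt(mean((v - mean(v))^2))) - 1) < 1e-9))
  }
  expect_equal(ncol(oligo_properties(2)), 38L)
  expect_equal(ncol(oligo_properties(3)), 12L)
})
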