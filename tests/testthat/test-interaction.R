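test_that("same-type strategies produce 2p / 2p / p^2 dimensions and values", {
  fa <- c(1, 2); fb <- c(3, 4)
  cc <- combine_same(fa, fb, "concat")
  expect_equal(as.numeric(cc$ab$values), c(1, 2, 3, 4))
  expect_equal(as.numeric(cc$ba$values), c(3, 4, 1, 2))
  expect_length(cc$ab$values, 4L)

  sp <- combine_same(fa, fb, "sumprod")
  expect_equal(as.numeric(sp$values), c(4, 6, 3, 8))
  expect_equal(as.numeric(combine_same(c(0, 0), c(0, 0), "sumprod")$values),
               rep(0, 4))

  tp <- combine_same(fa, fb, "tensor")
  expect_equal(as.numeric(tp$values), c(3, 4, 6, 8))  # k = (i-1)*p + j

  expect_error(combine_same(c(1, 2), c(1, 2, 3), "concat"), "equal dimension")
})

test_that("cross-type strategies produce p_t+p_d / p_t*p_d dimensions", {
  expect_length(combine_cross(1:3, 1:5, "concat")$values, 8L)
  expect_equal(as.numeric(combine_cross(c(2), c(1, 5), "tensor")$values),
               c(2, 10))
  expect_equal(as.numeric(combine_cross(c(1, 1), c(1, 1), "tensor")$values),
               rep(1, 4))
})

test_that("sumprod is exactly symmetric and concat orderings are block-reverses", {
  set.seed(99)
  for (rep in 1:20) {
    p <- sample(1:20, 1)
    a <- rnorm(p); b <- rnorm(p)
    expect_identical(as.numeric(combine_same(a, b, "sumprod")$values),
                     as.numeric(combine_same(b, a, "sumprod")$values))
    cc <- combine_same(a, b, "concat")
    expect_equal(as.numeric(cc$ab$values),
                 as.numeric(cc$ba$values)[c((p + 1):(2 * p), 1:p)])
  }
})

test_that("tensor products match the brute-force table and distribute sums", {
  set.seed(7)
  for (rep in 1:20) {
    pa <- sample(1:10, 1); pb <- sample(1:10, 1)
    a <- rnorm(pa); b <- rnorm(pb)
    tp <- combine_cross(a, b, "tensor")
    tab <- matrix(NA_real_, pa, pb)
    for (i in seq_len(pa)) for (j in seq_len(pb)) tab[i, j] <- a[i] * b[j]
    expect_equal(as.numeric(tp$values), as.vector(t(tab)), tolerance = 1e-12)
    expect_equal(sum(tp$values), sum(a) * sum(b), tolerance = 1e-10)
  }
})

test_that("dimensions conform for random operand sizes", {
  set.seed(123)
  for (rep in 1:50) {
    p <- sample(1:50, 1)
    a <- rnorm(p); b <- rnorm(p)
    expect_length(combine_same(a, b, "concat")$ab$values, 2L * p)
    expect_length(combine_same(a, b, "sumprod")$values, 2L * p)
    expect_length(combine_same(a, b, "tensor")$values, p^2)
    pt <- sample(1:50, 1); pd <- sample(1:50, 1)
    t_ <- rnorm(pt); d_ <- rnorm(pd)
    expect_length(combine_cross(t_, d_, "concat")$values, pt + pd)
    expect_length(combine_cross(t_, d_, "tensor")$values, pt * pd)
  }
})

test_that("pair features record strategy and operand provenance", {
  pf <- combine_cross(1:3, 1:2, "tensor", t_name = "prot1", d_name = "drugA")
  expect_s3_class(pf, "pair_feature")
  expect_equal(pf$strategy, "cross_tensor")
  expect_equal(pf$operand_a_name, "prot1")
  expect_equal(pf$operand_b_name, "drugA")
  expect_equal(pf$p_a, 3L)
  expect_equal(pf$p_b, 2L)
})
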