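# Interaction descriptors for pairwise samples: three same-type strategies
# (concatenation in both orderings, elementwise sum/product, tensor product)
# and two cross-type strategies (concatenation, tensor product).

new_pair_feature <- function(values, strategy, a_name, b_name, p_a, p_b) {
  structure(list(values = values, strategy = strategy,
                 operand_a_name = a_name, operand_b_name = b_name,
                 p_a = p_a, p_b = p_b),
            class = "pair_feature")
}

#' @export
print.pair_feature <- function(x, ...) {
  cat("<pair_feature> strategy=", x$strategy, " (", x$operand_a_name, " x ",
      x$operand_b_name, "), p_a=", x$p_a, ", p_b=", x$p_b,
      ", dim=", length(x$values), "\n", sep = "")
  invisible(x)
}

as_fv_operand <- function(f, default_prefix) {
  f <- unclass(f)
  if (is.null(names(f))) names(f) <- paste0(default_prefix, seq_along(f))
  feature_vector(f)
}

#' Combine two same-type feature vectors
#'
#' For operands F_a and F_b of equal dimension p:
#' `concat` returns BOTH orderings, F_ab = (F_a, F_b) and F_ba = (F_b, F_a),
#' each of dimension 2p; `sumprod` returns the elementwise sums followed by
#' the elementwise products (dimension 2p, symmetric in its operands);
#' `tensor` returns F(k) = F_a(i) * F_b(j) with k = (i - 1) * p + j
#' (dimension p^2).
#'
#' @param fa,fb numeric feature vectors of equal length.
#' @param strategy `"concat"`, `"sumprod"` or `"tensor"`.
#' @param a_name,b_name operand identities recorded in the result.
#' @return A `pair_feature` (for `concat`, a list of two: `ab` and `ba`).
#' @export
#' @examples
#' combine_same(c(1, 2), c(3, 4), "tensor")$values  # 3 4 6 8
combine_same <- function(fa, fb, strategy = c("concat", "sumprod", "tensor"),
                         a_name = "a", b_name = "b") {
  strategy <- match.arg(strategy)
  fa <- as_fv_operand(fa, "f")
  fb <- as_fv_operand(fb, "f")
  p <- length(fa)
  if (length(fb) != p)
    stop("same-type operands must have equal dimension: ", p, " vs ", length(fb))
  if (p < 1L) stop("empty operand")
  if (strategy == "concat") {
    ab <- feature_vector(c(unclass(fa), unclass(fb)),
                         c(paste0("a.", names(fa)), paste0("b.", names(fb))))
    ba <- feature_vector(c(unclass(fb), unclass(fa)),
                         c(paste0("b.", names(fb)), paste0("a.", names(fa))))
    return(list(ab = new_pair_feature(ab, "same_concat", a_name, b_name, p, p),
                ba = new_pair_feature(ba, "same_concat", b_name, a_name, p, p)))
  }
  if (strategy == "sumprod") {
    v <- feature_vector(c(unclass(fa) + unclass(fb), unclass(fa) * unclass(fb)),
                        c(paste0("sum.", names(fa)), paste0("prod.", names(fa))))
    return(new_pair_feature(v, "same_sumprod", a_name, b_name, p, p))
  }
  k <- as.vector(t(outer(unclass(fa), unclass(fb))))  # k = (i-1)*p + j
  nms <- as.vector(t(outer(names(fa), names(fb),
                           function(i, j) paste0("a.", i, "*b.", j))))
  new_pair_feature(feature_vector(k, nms), "same_tensor", a_name, b_name, p, p)
}

#' Combine two cross-type feature vectors
#'
#' For operands F_t (dimension p_t) and F_d (dimension p_d, possibly
#' different): `concat` returns (F_t, F_d) of dimension p_t + p_d; `tensor`
#' returns F(k) = F_t(i) * F_d(j) with row-major index k = (i - 1) * p_d + j
#' (dimension p_t * p_d).
#'
#' @param ft,fd numeric feature vectors (lengths may differ).
#' @param strategy `"concat"` or `"tensor"`.
#' @param t_name,d_name operand identities recorded in the result.
#' @return A `pair_feature`.
#' @export
combine_cross <- function(ft, fd, strategy = c("concat", "tensor"),
                          t_name = "t", d_name = "d") {
  strategy <- match.arg(strategy)
  ft <- as_fv_operand(ft, "t")
  fd <- as_fv_operand(fd, "d")
  pt <- length(ft); pd <- length(fd)
  if (pt < 1L || pd < 1L) stop("empty operand")
  if (strategy == "concat") {
    v <- feature_vector(c(unclass(ft), unclass(fd)),
                        c(paste0("t.", names(ft)), paste0("d.", names(fd))))
    return(new_pair_feature(v, "cross_concat", t_name, d_name, pt, pd))
  }
  k <- as.vector(t(outer(unclass(ft), unclass(fd))))  # k = (i-1)*p_d + j
  nms <- as.vector(t(outer(names(ft), names(fd),
                           function(i, j) paste0("t.", i, "*d.", j))))
  new_pair_feature(feature_vector(k, nms), "cross_tensor", t_name, d_name, pt, pd)
}
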