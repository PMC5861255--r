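# DNA descriptor families: k-mer compositions, dinucleotide/trinucleotide
# auto/cross covariance, and pseudo nucleotide compositions.
#
# Coordinates are 1-based in the formulas below and 0-based internally;
# only the forward strand is scanned (reverse complements matter only for
# canonical k-mer collapsing).

revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(s, ""), function(x) paste(rev(x), collapse = ""), character(1L)))
}

#' Bundled oligonucleotide property tables
#'
#' Standardized physicochemical index tables for dinucleotides (38 indices)
#' and trinucleotides (12 indices). The index values bundled with the
#' package are synthetic (seeded, frozen text files shipped in
#' `extdata/*_synthetic.tsv`): they are placeholders with the conventional
#' set sizes, z-scored over the 4^k oligonucleotides, not published
#' experimental scales. Supply your own table via `path` (wide tabular
#' text: an `oligo` column plus one column per property) for real indices.
#'
#' @param k oligonucleotide length, 2 or 3.
#' @param path optional path to a user property table.
#' @param standardized z-score each property over the 4^k oligos?
#' @return A matrix with 4^k rows (rownames the oligos in lexicographic
#'   order) and one column per property.
#' @export
oligo_properties <- function(k = 2L, path = NULL, standardized = TRUE) {
  k <- as.integer(k)
  if (!k %in% c(2L, 3L)) stop("k must be 2 or 3")
  if (is.null(path))
    path <- system.file("extdata",
                        sprintf("%snucleotide_properties_synthetic.tsv",
                                if (k == 2L) "di" else "tri"),
                        package = "biodesc", mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  oligos <- kmer_names(DNA_ALPHABET, k)
  key <- toupper(trimws(tab[[1L]]))
  if (!setequal(key, oligos) || anyDuplicated(key))
    stop("property table must have exactly one row per length-", k, " oligonucleotide")
  m <- as.matrix(tab[match(oligos, key), -1L, drop = FALSE])
  rownames(m) <- oligos
  if (ncol(m) < 1L) stop("property table has no property columns")
  if (standardized) {
    m <- apply(m, 2L, function(v) {
      sd0 <- sqrt(mean((v - mean(v))^2))
      if (sd0 == 0) stop("degenerate oligo property (zero variance)")
      (v - mean(v)) / sd0
    })
    rownames(m) <- oligos
  }
  m
}

#' k-mer composition of a DNA sequence
#'
#' Sliding-window counts of all 4^k k-mers in lexicographic order.
#' `normalize` divides by the window count L - k + 1; `canonical` merges
#' each k-mer with its reverse complement (palindromes map to themselves),
#' making the vector strand-symmetric.
#'
#' @param seq DNA sequence (string over ACGT).
#' @param k word size (>= 1).
#' @param canonical collapse reverse-complement pairs?
#' @param normalize report fractions instead of counts?
#' @return A [feature_vector()]; length 4^k, or the number of
#'   reverse-complement classes when `canonical`.
#' @export
kmer_composition <- function(seq, k = 2L, canonical = FALSE, normalize = TRUE) {
  seq <- as_dna(seq)
  k <- as.integer(k)
  L <- nchar(seq)
  if (k < 1L) stop("k must be >= 1")
  if (L < k) stop("sequence of length ", L, " is shorter than k = ", k)
  kmers <- kmer_names(DNA_ALPHABET, k)
  words <- substring(seq, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
  counts <- as.numeric(table(factor(words, levels = kmers)))
  if (canonical) {
    rc <- revcomp(kmers)
    canon <- ifelse(kmers <= rc, kmers, rc)
    classes <- unique(canon[order(match(canon, kmers))])
    counts <- vapply(classes, function(cl) sum(counts[canon == cl]), numeric(1L))
    kmers <- classes
  }
  if (normalize) counts <- counts / (L - k + 1L)
  prefix <- if (canonical) "rckmer" else "kmer"
  feature_vector(counts, paste0(prefix, k, ".", kmers))
}

# property profile: matrix [L-k+1, nprop] of oligo property values along seq
oligo_profile <- function(seq, k, props) {
  L <- nchar(seq)
  words <- substring(seq, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
  props[words, , drop = FALSE]
}

#' Oligonucleotide auto / cross covariance
#'
#' Let P_u(i) be property u of the k-mer starting at position i and Pbar_u
#' its mean over the L - k + 1 positions. Then for lag d = 1..maxlag:
#' auto covariance AC(u, d) = sum_{i=1}^{L-k-d+1}
#' (P_u(i) - Pbar_u)(P_u(i+d) - Pbar_u) / (L - k - d + 1); cross covariance
#' CC(u1, u2, d) is the analogue over ordered pairs of distinct properties;
#' `autocross` concatenates auto then cross. Defaults (38 dinucleotide or
#' 12 trinucleotide properties, maxlag 2) give lengths 76 / 2812 / 2888 for
#' k = 2 and 24 / 264 / 288 for k = 3.
#'
#' @param seq DNA sequence.
#' @param k oligonucleotide length, 2 or 3.
#' @param mode `"auto"`, `"cross"` or `"autocross"`.
#' @param props property matrix as from [oligo_properties()] (standardized).
#' @param maxlag maximum lag; requires L >= k + maxlag + 1.
#' @return A [feature_vector()].
#' @export
covariance <- function(seq, k = 2L, mode = c("auto", "cross", "autocross"),
                       props = oligo_properties(k), maxlag = 2L) {
  mode <- match.arg(mode)
  seq <- as_dna(seq)
  k <- as.integer(k)
  L <- nchar(seq)
  if (L < k + maxlag + 1L)
    stop("sequence too short: need L >= k + maxlag + 1 = ", k + maxlag + 1L)
  if (mode %in% c("cross", "autocross") && ncol(props) < 2L)
    stop("cross covariance requires at least 2 properties")
  prof <- oligo_profile(seq, k, props)
  n <- nrow(prof)
  cen <- sweep(prof, 2L, colMeans(prof))
  pn <- colnames(props)
  out <- numeric(0); nms <- character(0)
  if (mode %in% c("auto", "autocross")) {
    for (u in seq_len(ncol(props))) for (d in seq_len(maxlag)) {
      i <- seq_len(n - d)
      out <- c(out, sum(cen[i, u] * cen[i + d, u]) / (n - d))
      nms <- c(nms, paste0(if (k == 2L) "dac." else "tac.", pn[u], ".lag", d))
    }
  }
  if (mode %in% c("cross", "autocross")) {
    for (u1 in seq_len(ncol(props))) for (u2 in seq_len(ncol(props))) {
      if (u1 == u2) next
      for (d in seq_len(maxlag)) {
        i <- seq_len(n - d)
        out <- c(out, sum(cen[i, u1] * cen[i + d, u2]) / (n - d))
        nms <- c(nms, paste0(if (k == 2L) "dcc." else "tcc.",
                             pn[u1], ".", pn[u2], ".lag", d))
      }
    }
  }
  if (mode == "autocross") nms <- paste0(sub("^(dac|tac|dcc|tcc)", "acc.\\1", nms))
  feature_vector(out, nms)
}

#' Pseudo nucleotide composition
#'
#' Parallel correlation: tier factors
#' theta_j = (1/(L-k-j+1)) sum_i Theta(i, i+j), where Theta is the mean
#' squared difference of the (standardized) property vectors of the two
#' k-mers; the output is the 4^k k-mer frequencies and the lambda factors
#' over Chou's common denominator (dimension 4^k + lambda, sums to 1).
#' Series correlation: one factor per (property, lag) pair in lag-major
#' order, dimension 4^k + lambda * ncol(props). Defaults k = 2, lambda = 2,
#' w = 0.05 give the 18-value pseudo dinucleotide composition; k = 3
#' parallel gives 66, k = 3 series gives 88.
#'
#' @param seq DNA sequence.
#' @param k oligonucleotide length, 2 or 3.
#' @param lambda number of correlation tiers (>= 1); requires L >= k + lambda.
#' @param w weight of the sequence-order effect (> 0).
#' @param props property matrix as from [oligo_properties()].
#' @param correlation `"parallel"` or `"series"`.
#' @return A [feature_vector()] summing to 1.
#' @export
pse_composition <- function(seq, k = 2L, lambda = 2L, w = 0.05,
                            props = oligo_properties(k),
                            correlation = c("parallel", "series")) {
  correlation <- match.arg(correlation)
  seq <- as_dna(seq)
  k <- as.integer(k)
  if (lambda < 1L) stop("lambda must be >= 1")
  if (w <= 0) stop("w must be > 0")
  L <- nchar(seq)
  if (L < k + lambda)
    stop("sequence too short: need L >= k + lambda = ", k + lambda)
  prof <- oligo_profile(seq, k, props)
  n <- nrow(prof)
  freq <- unclass(kmer_composition(seq, k, canonical = FALSE, normalize = TRUE))
  oligos <- kmer_names(DNA_ALPHABET, k)
  prefix <- paste0(if (k == 2L) "psednc" else "psetnc",
                   if (correlation == "series") ".sc" else "")
  if (correlation == "parallel") {
    theta <- vapply(seq_len(lambda), function(j) {
      i <- seq_len(n - j)
      mean(rowMeans((prof[i, , drop = FALSE] - prof[i + j, , drop = FALSE])^2))
    }, numeric(1L))
    nms <- c(paste0(prefix, ".", oligos), paste0(prefix, ".theta", seq_len(lambda)))
  } else {
    theta <- numeric(0); tn <- character(0)
    for (j in seq_len(lambda)) {
      i <- seq_len(n - j)
      for (u in seq_len(ncol(prof))) {
        theta <- c(theta, mean(prof[i, u] * prof[i + j, u]))
        tn <- c(tn, paste0(prefix, ".", colnames(prof)[u], ".tau", j))
      }
    }
    nms <- c(paste0(prefix, ".", oligos), tn)
  }
  denom <- sum(freq) + w * sum(theta)
  if (denom <= 0) stop("degenerate pseudo-composition normalization")
  feature_vector(c(freq / denom, w * theta / denom), nms)
}

#' All DNA descriptor families at their defaults
#'
#' Concatenates, in fixed order: basic 2-mer composition (16),
#' reverse-complement 2-mer composition (10), dinucleotide auto / cross /
#' auto-cross covariance (76 / 2812 / 2888), trinucleotide auto / cross /
#' auto-cross covariance (24 / 264 / 288), pseudo dinucleotide composition
#' (18), parallel-correlation pseudo trinucleotide composition (66) and the
#' two series-correlation pseudo compositions (92 and 88): 6642 values.
#'
#' @param seq DNA sequence; the trinucleotide pseudo composition at
#'   lambda = 2 plus the covariance preconditions require length >= 10.
#' @return A [feature_vector()] with globally unique names.
#' @export
dna_all <- function(seq) {
  seq <- as_dna(seq)
  if (nchar(seq) < 10L)
    stop("dna_all requires length >= 10 (trinucleotide covariance at maxlag 2); got ",
         nchar(seq))
  p2 <- oligo_properties(2L)
  p3 <- oligo_properties(3L)
  fv_concat(list(
    kmer_composition(seq, 2L),
    kmer_composition(seq, 2L, canonical = TRUE),
    covariance(seq, 2L, "auto", p2),
    covariance(seq, 2L, "cross", p2),
    covariance(seq, 2L, "autocross", p2),
    covariance(seq, 3L, "auto", p3),
    covariance(seq, 3L, "cross", p3),
    covariance(seq, 3L, "autocross", p3),
    pse_composition(seq, 2L, props = p2),
    pse_composition(seq, 3L, props = p3),
    pse_composition(seq, 2L, props = p2, correlation = "series"),
    pse_composition(seq, 3L, props = p3, correlation = "series")))
}
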