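# Protein descriptor families: k-peptide compositions, three
# autocorrelations, CTD, conjoint triads, sequence-order-coupling numbers,
# quasi-sequence-order and two pseudo amino acid composition modes.

seq_chars <- function(seq) strsplit(seq, "")[[1L]]

#' k-peptide composition
#'
#' Fraction of each of the 20^k k-mers over the L - k + 1 sliding windows,
#' in fixed lexicographic order (dimension 20, 400 or 8000 for k = 1, 2, 3).
#'
#' @param seq protein sequence (string).
#' @param k word size, 1, 2 or 3.
#' @return A [feature_vector()] of length `20^k` summing to 1.
#' @export
#' @examples
#' peptide_composition("MKM", k = 2)[c("MK", "KM")]
peptide_composition <- function(seq, k = 1L) {
  seq <- as_protein(seq)
  k <- as.integer(k)
  if (!k %in% 1:3) stop("k must be 1, 2 or 3")
  L <- nchar(seq)
  if (L < k) stop("sequence of length ", L, " is shorter than k = ", k)
  kmers <- kmer_names(AA_ALPHABET, k)
  words <- substring(seq, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
  counts <- table(factor(words, levels = kmers))
  feature_vector(as.numeric(counts) / (L - k + 1L), kmers)
}

# all k-mers over an alphabet in lexicographic order
kmer_names <- function(alphabet, k) {
  if (k == 1L) return(alphabet)
  grid <- do.call(expand.grid,
                  c(rev(replicate(k, alphabet, simplify = FALSE)),
                    list(stringsAsFactors = FALSE)))
  apply(grid[, rev(seq_len(k)), drop = FALSE], 1L, paste, collapse = "")
}

#' Sequence autocorrelation descriptors
#'
#' Normalized Moreau-Broto, Moran or Geary autocorrelation of standardized
#' per-residue property scales at lags 1..maxlag. With the default octet of
#' scales and maxlag 30 each flavour has 240 values.
#'
#' Moreau-Broto: AC(d) = sum_{i=1}^{L-d} P_i P_{i+d} / (L - d).
#' Moran: I(d) = [sum (P_i - Pbar)(P_{i+d} - Pbar)/(L-d)] / [sum (P_i - Pbar)^2 / L].
#' Geary: C(d) = [sum (P_i - P_{i+d})^2 / (2(L-d))] / [sum (P_i - Pbar)^2 / (L-1)].
#' Pbar is the mean over the sequence. If the sequence has zero property
#' variance, Moran and Geary are reported as 0 (degenerate rule).
#'
#' @param seq protein sequence.
#' @param kind one of `"moreau_broto"`, `"moran"`, `"geary"`.
#' @param properties named list of per-residue scales (standardized); default
#'   the bundled octet.
#' @param maxlag maximum lag (must be < sequence length).
#' @return A [feature_vector()] of length `length(properties) * maxlag`.
#' @export
autocorrelation <- function(seq, kind = c("moreau_broto", "moran", "geary"),
                            properties = aa_properties("autocorrelation"),
                            maxlag = 30L) {
  kind <- match.arg(kind)
  seq <- as_protein(seq)
  L <- nchar(seq)
  if (maxlag >= L) stop("maxlag (", maxlag, ") must be < sequence length (", L, ")")
  chars <- seq_chars(seq)
  out <- numeric(0)
  nms <- character(0)
  for (pname in names(properties)) {
    P <- unname(properties[[pname]][chars])
    Pbar <- mean(P)
    dev <- P - Pbar
    ss <- sum(dev^2)
    vals <- vapply(seq_len(maxlag), function(d) {
      i <- seq_len(L - d)
      switch(kind,
        moreau_broto = sum(P[i] * P[i + d]) / (L - d),
        moran = if (ss == 0) 0 else
          (sum(dev[i] * dev[i + d]) / (L - d)) / (ss / L),
        geary = if (ss == 0) 0 else
          (sum((P[i] - P[i + d])^2) / (2 * (L - d))) / (ss / (L - 1)))
    }, numeric(1L))
    out <- c(out, vals)
    nms <- c(nms, paste0(kind, ".", pname, ".lag", seq_len(maxlag)))
  }
  feature_vector(out, nms)
}

#' Composition / Transition / Distribution (CTD) descriptors
#'
#' For each of seven three-class physicochemical partitions of the alphabet:
#' Composition (class counts / L, 3 values), Transition
#' T(r,s) = (N_rs + N_sr) / (L - 1) for the three unordered class pairs, and
#' Distribution (for each class the 1-based positions of the first, 25%, 50%,
#' 75% and 100% occurrence divided by L, times 100; 0 for absent classes).
#' Total length 21 + 21 + 105 = 147.
#'
#' @param seq protein sequence.
#' @param groupings list of 7 attribute groupings; default [ctd_groupings()].
#' @return A [feature_vector()] of length 147.
#' @export
ctd <- function(seq, groupings = ctd_groupings()) {
  seq <- as_protein(seq)
  if (length(groupings) != 7L) stop("ctd requires exactly 7 attribute groupings")
  L <- nchar(seq)
  if (L < 2L) stop("ctd requires a sequence of length >= 2")
  chars <- seq_chars(seq)
  comp <- trans <- dist <- numeric(0)
  cn <- tn <- dn <- character(0)
  for (g in groupings) {
    cls <- integer(L)
    for (j in 1:3) cls[chars %in% g$classes[[j]]] <- j
    comp <- c(comp, vapply(1:3, function(j) sum(cls == j) / L, numeric(1L)))
    cn <- c(cn, paste0("ctd.comp.", g$attribute, ".c", 1:3))
    pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
    a <- cls[-L]; b <- cls[-1L]
    trans <- c(trans, vapply(pairs, function(p)
      sum((a == p[1L] & b == p[2L]) | (a == p[2L] & b == p[1L])) / (L - 1L),
      numeric(1L)))
    tn <- c(tn, paste0("ctd.trans.", g$attribute, ".c",
                       vapply(pairs, function(p) paste0(p[1L], p[2L]), character(1L))))
    for (j in 1:3) {
      pos <- which(cls == j)
      q <- if (length(pos) == 0L) rep(0, 5L) else {
        n <- length(pos)
        idx <- pmax(1L, ceiling(c(1e-9, 0.25, 0.5, 0.75, 1) * n))
        100 * pos[idx] / L
      }
      dist <- c(dist, q)
      dn <- c(dn, paste0("ctd.dist.", g$attribute, ".c", j, ".p",
                         c("first", "25", "50", "75", "100")))
    }
  }
  feature_vector(c(comp, trans, dist), c(cn, tn, dn))
}

#' Conjoint triad descriptors
#'
#' Residues are mapped to 7 electrostatic/volume classes; the descriptor is
#' the raw count of each of the 7^3 = 343 class triads over all L - 2
#' windows, in fixed order (class indices varying fastest on the right).
#'
#' @param seq protein sequence (length >= 3).
#' @return A [feature_vector()] of length 343 of nonnegative counts.
#' @export
conjoint_triad <- function(seq) {
  seq <- as_protein(seq)
  L <- nchar(seq)
  if (L < 3L) stop("conjoint triads require length >= 3")
  chars <- seq_chars(seq)
  cls <- integer(L)
  for (j in seq_along(TRIAD_CLASSES)) cls[chars %in% TRIAD_CLASSES[[j]]] <- j
  key <- (cls[1:(L - 2L)] - 1L) * 49L + (cls[2:(L - 1L)] - 1L) * 7L + cls[3:L]
  counts <- tabulate(key, nbins = 343L)
  grid <- expand.grid(k = 1:7, j = 1:7, i = 1:7)
  nms <- paste0("triad.", grid$i, ".", grid$j, ".", grid$k)
  feature_vector(counts, nms)
}

#' Sequence-order-coupling numbers
#'
#' tau_d = sum_{i=1}^{L-d} d(R_i, R_{i+d})^2 for d = 1..maxlag, per distance
#' matrix. With the two bundled matrices and maxlag 30 the output has 60
#' values.
#'
#' @param seq protein sequence.
#' @param matrices named list of 20 x 20 residue distance matrices; default
#'   [aa_distance_matrices()].
#' @param maxlag maximum lag (< sequence length).
#' @return A [feature_vector()] of nonnegative coupling numbers.
#' @export
socn <- function(seq, matrices = aa_distance_matrices(), maxlag = 30L) {
  seq <- as_protein(seq)
  L <- nchar(seq)
  if (maxlag >= L) stop("maxlag (", maxlag, ") must be < sequence length (", L, ")")
  chars <- seq_chars(seq)
  out <- numeric(0); nms <- character(0)
  for (mname in names(matrices)) {
    m <- matrices[[mname]]
    vals <- vapply(seq_len(maxlag), function(d) {
      i <- seq_len(L - d)
      sum(m[cbind(chars[i], chars[i + d])]^2)
    }, numeric(1L))
    out <- c(out, vals)
    nms <- c(nms, paste0("socn.", mname, ".d", seq_len(maxlag)))
  }
  feature_vector(out, nms)
}

#' Quasi-sequence-order descriptors
#'
#' Per distance matrix: the first 20 values are f_r / (sum_s f_s +
#' w * sum_d tau_d) over the residue frequencies f, and the next maxlag
#' values are w * tau_d over the same denominator, so each per-matrix block
#' sums to 1. Defaults (2 matrices, maxlag 30, w = 0.1) give 100 values.
#'
#' @inheritParams socn
#' @param w weight of the sequence-order effect (> 0).
#' @return A [feature_vector()] of length `length(matrices) * (20 + maxlag)`.
#' @export
qso <- function(seq, matrices = aa_distance_matrices(), maxlag = 30L, w = 0.1) {
  seq <- as_protein(seq)
  if (w <= 0) stop("w must be > 0")
  L <- nchar(seq)
  if (maxlag >= L) stop("maxlag (", maxlag, ") must be < sequence length (", L, ")")
  chars <- seq_chars(seq)
  f <- as.numeric(table(factor(chars, levels = AA_ALPHABET)))
  tau_all <- socn(seq, matrices, maxlag)
  out <- numeric(0); nms <- character(0)
  for (mname in names(matrices)) {
    tau <- unclass(tau_all)[paste0("socn.", mname, ".d", seq_len(maxlag))]
    denom <- sum(f) + w * sum(tau)
    out <- c(out, f / denom, w * tau / denom)
    nms <- c(nms, paste0("qso.", mname, ".", AA_ALPHABET),
             paste0("qso.", mname, ".tau", seq_len(maxlag)))
  }
  feature_vector(out, nms)
}

# shared Chou-style normalization: frequencies + weighted correlation factors
chou_normalize <- function(freq, theta, w) {
  denom <- sum(freq) + w * sum(theta)
  c(freq / denom, w * theta / denom)
}

#' Pseudo amino acid composition (parallel-correlation PseAAC)
#'
#' Correlation factors theta_j = (1/(L-j)) sum_i Theta(R_i, R_{i+j}), where
#' Theta(a, b) is the mean over the property scales of (P(a) - P(b))^2
#' computed on standardized scales. The output is the 20 residue frequencies
#' and the lambda factors under Chou's common-denominator normalization;
#' defaults (lambda = 30, w = 0.05, the hydrophobicity / hydrophilicity /
#' side-chain mass triple) give 20 + 30 = 50 values summing to 1.
#'
#' @param seq protein sequence.
#' @param lambda number of correlation tiers (< sequence length).
#' @param w weight of the sequence-order effect (> 0).
#' @param properties named list of standardized property scales.
#' @return A [feature_vector()] of length `20 + lambda`.
#' @export
pseaac <- function(seq, lambda = 30L, w = 0.05,
                   properties = aa_properties("pseaac")) {
  seq <- as_protein(seq)
  if (w <= 0) stop("w must be > 0")
  L <- nchar(seq)
  if (lambda >= L) stop("lambda (", lambda, ") must be < sequence length (", L, ")")
  chars <- seq_chars(seq)
  P <- vapply(properties, function(p) unname(p[chars]), numeric(L))
  theta <- vapply(seq_len(lambda), function(j) {
    i <- seq_len(L - j)
    mean(rowMeans((P[i, , drop = FALSE] - P[i + j, , drop = FALSE])^2))
  }, numeric(1L))
  f <- as.numeric(table(factor(chars, levels = AA_ALPHABET))) / L
  feature_vector(chou_normalize(f, theta, w),
                 c(paste0("pseaac.", AA_ALPHABET),
                   paste0("pseaac.theta", seq_len(lambda))))
}

#' Amphiphilic pseudo amino acid composition
#'
#' The amphiphilic variant computes one correlation factor per (scale, lag)
#' pair for hydrophobicity and hydrophilicity separately, using the mean of
#' the products P(R_i) * P(R_{i+j}) along the sequence, giving 2 * lambda
#' pseudo components. Default lambda = 15 gives 20 + 30 = 50 values.
#'
#' @inheritParams pseaac
#' @return A [feature_vector()] of length `20 + 2 * lambda`.
#' @export
apseaac <- function(seq, lambda = 15L, w = 0.05) {
  seq <- as_protein(seq)
  if (w <= 0) stop("w must be > 0")
  L <- nchar(seq)
  if (lambda >= L) stop("lambda (", lambda, ") must be < sequence length (", L, ")")
  chars <- seq_chars(seq)
  props <- aa_properties("pseaac")[c("hydrophobicity", "hydrophilicity")]
  tau <- numeric(0); nms <- character(0)
  for (j in seq_len(lambda)) {
    i <- seq_len(L - j)
    for (pname in names(props)) {
      P <- unname(props[[pname]][chars])
      tau <- c(tau, mean(P[i] * P[i + j]))
      nms <- c(nms, paste0("apseaac.", pname, ".tau", j))
    }
  }
  f <- as.numeric(table(factor(chars, levels = AA_ALPHABET))) / L
  denom <- sum(f) + w * sum(tau)
  if (denom <= 0)
    stop("degenerate amphiphilic normalization (non-positive denominator)")
  feature_vector(c(f / denom, w * tau / denom),
                 c(paste0("apseaac.", AA_ALPHABET), nms))
}

#' All protein descriptor families at their defaults
#'
#' Concatenates, in order: amino acid / dipeptide / tripeptide composition,
#' the three autocorrelations, CTD, conjoint triads, SOCN, QSO, PseAAC and
#' amphiphilic PseAAC, all at default parameters (9890 values). Requires a
#' sequence longer than the largest default lag (30).
#'
#' @param seq protein sequence of length > 30.
#' @return A [feature_vector()] with globally unique names.
#' @export
protein_all <- function(seq) {
  seq <- as_protein(seq)
  L <- nchar(seq)
  if (L <= 30L)
    stop("protein_all requires length > 30 (autocorrelation/SOCN/PseAAC lag 30); got ", L)
  aac <- peptide_composition(seq, 1L)
  names(aac) <- paste0("aac.", names(aac))
  dpc <- peptide_composition(seq, 2L)
  names(dpc) <- paste0("dpc.", names(dpc))
  tpc <- peptide_composition(seq, 3L)
  names(tpc) <- paste0("tpc.", names(tpc))
  fv_concat(list(
    aac, dpc, tpc,
    autocorrelation(seq, "moreau_broto"),
    autocorrelation(seq, "moran"),
    autocorrelation(seq, "geary"),
    ctd(seq),
    conjoint_triad(seq),
    socn(seq),
    qso(seq),
    pseaac(seq),
    apseaac(seq)))
}
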