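# Bundled per-residue physicochemical constants.
#
# Residue order everywhere is alphabetical one-letter: ACDEFGHIKLMNPQRSTVWY.
# Raw scales are bundled as-is; descriptor code standardizes on demand
# (z-score over the 20 residues, population SD).

aa_vec <- function(...) {
  v <- c(...)
  stopifnot(length(v) == 20L, setequal(names(v), AA_ALPHABET))
  v[AA_ALPHABET]
}

# Eight classic AAindex-style scales driving the autocorrelation octet
# (hydrophobicity, average flexibility, polarizability, free energy of
# solution, accessible surface area, residue volume, steric parameter,
# relative mutability). 8 scales x 30 lags = the 240-value default.
AA_AUTOCORR_PROPERTIES <- list(
  hydrophobicity = aa_vec(
    A = 0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19, G = 0.48, H = -0.40,
    I = 1.38, K = -1.50, L = 1.06, M = 0.64, N = -0.78, P = 0.12, Q = -0.85,
    R = -2.53, S = -0.18, T = -0.05, V = 1.08, W = 0.81, Y = 0.26),
  flexibility = aa_vec(
    A = 0.357, C = 0.346, D = 0.511, E = 0.497, F = 0.314, G = 0.544,
    H = 0.323, I = 0.462, K = 0.466, L = 0.365, M = 0.295, N = 0.463,
    P = 0.509, Q = 0.493, R = 0.529, S = 0.507, T = 0.444, V = 0.386,
    W = 0.305, Y = 0.420),
  polarizability = aa_vec(
    A = 0.046, C = 0.128, D = 0.105, E = 0.151, F = 0.290, G = 0.000,
    H = 0.230, I = 0.186, K = 0.219, L = 0.186, M = 0.221, N = 0.134,
    P = 0.131, Q = 0.180, R = 0.291, S = 0.062, T = 0.108, V = 0.140,
    W = 0.409, Y = 0.298),
  free_energy = aa_vec(
    A = -0.368, C = 4.530, D = 2.060, E = 1.770, F = 1.060, G = -0.525,
    H = 0.000, I = 0.791, K = 0.000, L = 1.070, M = 0.656, N = 0.000,
    P = -2.240, Q = 0.731, R = -1.030, S = -0.524, T = 0.000, V = 0.401,
    W = 1.600, Y = 4.910),
  surface_area = aa_vec(
    A = 115, C = 135, D = 150, E = 190, F = 210, G = 75, H = 195, I = 175,
    K = 200, L = 170, M = 185, N = 160, P = 145, Q = 180, R = 225, S = 115,
    T = 140, V = 155, W = 255, Y = 230),
  residue_volume = aa_vec(
    A = 52.6, C = 68.3, D = 68.4, E = 84.7, F = 113.9, G = 36.3, H = 91.9,
    I = 102.0, K = 105.1, L = 102.0, M = 97.7, N = 75.7, P = 73.6, Q = 89.7,
    R = 109.1, S = 54.9, T = 71.2, V = 85.1, W = 135.4, Y = 116.2),
  steric = aa_vec(
    A = 0.52, C = 0.62, D = 0.76, E = 0.68, F = 0.70, G = 0.00, H = 0.70,
    I = 1.02, K = 0.68, L = 0.98, M = 0.78, N = 0.76, P = 0.36, Q = 0.68,
    R = 0.68, S = 0.53, T = 0.50, V = 0.76, W = 0.70, Y = 0.70),
  mutability = aa_vec(
    A = 100, C = 20, D = 106, E = 102, F = 41, G = 49, H = 66, I = 96,
    K = 56, L = 40, M = 94, N = 134, P = 56, Q = 93, R = 65, S = 120,
    T = 97, V = 74, W = 18, Y = 41)
)

# Chou's pseudo amino acid composition triple: hydrophobicity,
# hydrophilicity (Hopp-Woods) and side-chain mass.
AA_PSEAAC_PROPERTIES <- list(
  hydrophobicity = AA_AUTOCORR_PROPERTIES$hydrophobicity,
  hydrophilicity = aa_vec(
    A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5, G = 0.0, H = -0.5,
    I = -1.8, K = 3.0, L = -1.8, M = -1.3, N = 0.2, P = 0.0, Q = 0.2,
    R = 3.0, S = 0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3),
  side_chain_mass = aa_vec(
    A = 15, C = 47, D = 59, E = 73, F = 91, G = 1, H = 82, I = 57, K = 73,
    L = 57, M = 75, N = 58, P = 42, Q = 72, R = 101, S = 31, T = 45,
    V = 43, W = 130, Y = 107)
)

# z-score a per-residue scale over the 20 residues (population SD)
standardize_property <- function(p) {
  mu <- mean(p)
  sd0 <- sqrt(mean((p - mu)^2))
  if (sd0 == 0) stop("degenerate property scale (zero variance)")
  (p - mu) / sd0
}

#' Bundled amino-acid property scales
#'
#' Returns the bundled per-residue physicochemical scales, optionally
#' z-scored over the 20 residues (population standard deviation), as the
#' normalized autocorrelation descriptors require.
#'
#' @param set `"autocorrelation"` for the eight-scale octet or `"pseaac"`
#'   for Chou's hydrophobicity / hydrophilicity / side-chain mass triple.
#' @param standardized standardize each scale before returning?
#' @return Named list of named numeric vectors over `ACDEFGHIKLMNPQRSTVWY`.
#' @export
aa_properties <- function(set = c("autocorrelation", "pseaac"),
                          standardized = TRUE) {
  set <- match.arg(set)
  tabs <- if (set == "autocorrelation") AA_AUTOCORR_PROPERTIES else AA_PSEAAC_PROPERTIES
  if (standardized) lapply(tabs, standardize_property) else tabs
}

#' Read a user property scale from a two-column file
#'
#' Accepts whitespace- or tab-separated text with exactly 20 rows of
#' (residue, value); validates that the residues are exactly the canonical
#' alphabet.
#'
#' @param path file path.
#' @return Named numeric vector over the 20 residues.
#' @export
read_aa_property <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("residue", "value"))
  res <- toupper(trimws(tab$residue))
  if (nrow(tab) != 20L || !setequal(res, AA_ALPHABET) || anyDuplicated(res))
    stop("property table must have exactly one row per canonical residue")
  stats::setNames(tab$value[match(AA_ALPHABET, res)], AA_ALPHABET)
}

# --- CTD attribute groupings: 7 attributes x 3 disjoint exhaustive classes ---
ctd_grouping <- function(attribute, g1, g2, g3) {
  classes <- lapply(list(g1, g2, g3), function(s) strsplit(s, "")[[1L]])
  all20 <- sort(unlist(classes))
  if (!identical(all20, sort(AA_ALPHABET)))
    stop("grouping for ", attribute, " is not a partition of the alphabet")
  list(attribute = attribute, classes = classes)
}

CTD_GROUPINGS <- list(
  ctd_grouping("hydrophobicity", "RKEDQN", "GASTPHY", "CLVIMFW"),
  ctd_grouping("vdw_volume", "GASCTPD", "NVEQIL", "MHKFRYW"),
  ctd_grouping("polarity", "LIFWCMVY", "PATGS", "HQRKNED"),
  ctd_grouping("polarizability", "GASDT", "CPNVEQIL", "KMHFRYW"),
  ctd_grouping("charge", "KR", "ANCQGHILMFPSTWYV", "DE"),
  ctd_grouping("secondary_structure", "EALMQKRH", "VIYCWFT", "GNPSD"),
  ctd_grouping("solvent_accessibility", "ALFCGIVW", "RKQEND", "MSPTHY")
)

#' Bundled CTD attribute groupings
#'
#' Seven three-class physicochemical partitions of the amino-acid alphabet
#' (hydrophobicity, normalized van der Waals volume, polarity,
#' polarizability, charge, secondary structure, solvent accessibility).
#'
#' @return List of 7 groupings, each a list with `attribute` and `classes`.
#' @export
ctd_groupings <- function() CTD_GROUPINGS

# Conjoint-triad residue classes (electrostatic/volume 7-class scheme)
TRIAD_CLASSES <- list(
  c("A", "G", "V"), c("I", "L", "F", "P"), c("Y", "M", "T", "S"),
  c("H", "N", "Q", "W"), c("R", "K"), c("D", "E"), c("C"))

# --- Residue distance matrices driving SOCN / QSO -------------------------

# Grantham (1974) distance recomputed from his printed formula
# D_ij = rho * [alpha (c_i-c_j)^2 + beta (p_i-p_j)^2 + gamma (v_i-v_j)^2]^(1/2)
# with composition c, polarity p, volume v; rho scales the mean over
# distinct pairs to 100.
grantham_matrix <- function() {
  c_ <- aa_vec(A = 0.00, C = 2.75, D = 1.38, E = 0.92, F = 0.00, G = 0.74,
               H = 0.58, I = 0.00, K = 0.33, L = 0.00, M = 0.00, N = 1.33,
               P = 0.39, Q = 0.89, R = 0.65, S = 1.42, T = 0.71, V = 0.00,
               W = 0.13, Y = 0.20)
  p_ <- aa_vec(A = 8.1, C = 5.5, D = 13.0, E = 12.3, F = 5.2, G = 9.0,
               H = 10.4, I = 5.2, K = 11.3, L = 4.9, M = 5.7, N = 11.6,
               P = 8.0, Q = 10.5, R = 10.5, S = 9.2, T = 8.6, V = 5.9,
               W = 5.4, Y = 6.2)
  v_ <- aa_vec(A = 31, C = 55, D = 54, E = 83, F = 132, G = 3, H = 96,
               I = 111, K = 119, L = 111, M = 105, N = 56, P = 32.5,
               S = 32, Q = 85, R = 124, T = 61, V = 84, W = 170, Y = 136)
  alpha <- 1.833; beta <- 0.1018; gamma <- 0.000399
  d <- sqrt(alpha * outer(c_, c_, "-")^2 +
            beta  * outer(p_, p_, "-")^2 +
            gamma * outer(v_, v_, "-")^2)
  rho <- 100 / mean(d[upper.tri(d)])
  m <- rho * d
  dimnames(m) <- list(AA_ALPHABET, AA_ALPHABET)
  m
}

# Synthetic physicochemical distance (stand-in for the published
# Schneider-Wrede matrix, which is not redistributable here): Euclidean
# distance over the z-scored Chou triple, normalized to max 1.
physchem_synthetic_matrix <- function() {
  p <- aa_properties("pseaac", standardized = TRUE)
  m <- sqrt(outer(p[[1L]], p[[1L]], "-")^2 +
            outer(p[[2L]], p[[2L]], "-")^2 +
            outer(p[[3L]], p[[3L]], "-")^2)
  m <- m / max(m)
  dimnames(m) <- list(AA_ALPHABET, AA_ALPHABET)
  m
}

#' Bundled residue distance matrices
#'
#' The two 20 x 20 matrices driving the sequence-order-coupling numbers:
#' the Grantham chemical distance (recomputed from composition, polarity
#' and volume) and a synthetic physicochemical distance built from the
#' z-scored PseAAC property triple (a stand-in constructed in this package,
#' not the published Schneider-Wrede matrix).
#'
#' @return Named list of two 20 x 20 numeric matrices with zero diagonals.
#' @export
aa_distance_matrices <- function() {
  list(physchem_synthetic = physchem_synthetic_matrix(),
       grantham = grantham_matrix())
}
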