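# Shared graph utilities for the chemical descriptor families.

# neighbor lists with bond orders / aromatic flags
mol_neighbors <- function(mol) {
  n <- mol$n_atoms
  nb <- vector("list", n)
  for (i in seq_len(mol$n_bonds)) {
    a <- mol$bonds$a1[i]; b <- mol$bonds$a2[i]
    nb[[a]] <- rbind(nb[[a]], c(b, mol$bonds$order[i], mol$bonds$aromatic[i]))
    nb[[b]] <- rbind(nb[[b]], c(a, mol$bonds$order[i], mol$bonds$aromatic[i]))
  }
  lapply(nb, function(x) if (is.null(x))
    matrix(numeric(0), ncol = 3L,
           dimnames = list(NULL, c("atom", "order", "aromatic")))
    else matrix(x, ncol = 3L,
                dimnames = list(NULL, c("atom", "order", "aromatic"))))
}

# sp / sp2 / sp3 from bond orders and aromaticity
hybridization <- function(mol) {
  nb <- mol_neighbors(mol)
  vapply(seq_len(mol$n_atoms), function(i) {
    if (nrow(nb[[i]]) == 0L) return("sp3")
    orders <- nb[[i]][, "order"]
    if (any(orders == 3L) || sum(orders == 2L) >= 2L) "sp"
    else if (any(orders == 2L) || mol$atoms$aromatic[i]) "sp2"
    else "sp3"
  }, character(1L))
}

# Kier-Hall valence delta: (Zv - nH) for second-row atoms,
# (Zv - nH)/(Z - Zv - 1) below
VALENCE_ELECTRONS <- c(H = 1, B = 3, C = 4, N = 5, O = 6, F = 7, Si = 4,
                       P = 5, S = 6, Cl = 7, Se = 6, Br = 7, As = 5, I = 7)

valence_delta <- function(mol) {
  vapply(seq_len(mol$n_atoms), function(i) {
    el <- mol$atoms$element[i]
    zv <- VALENCE_ELECTRONS[el]
    if (is.na(zv)) return(mol$atoms$degree[i])  # metals: plain degree
    z <- ELEMENTS[el, "Z"]
    h <- mol$atoms$nH[i]
    if (z <= 10) max(zv - h, 0) else max((zv - h) / (z - zv - 1), 0)
  }, numeric(1L))
}

# principal quantum number per element (for intrinsic E-state)
quantum_n <- function(symbols) {
  z <- element_prop(symbols, "Z", default = 6)
  findInterval(z, c(1, 3, 11, 19, 37, 55))
}

# all simple paths with 1..maxlen edges, each undirected path counted once
mol_paths <- function(mol, maxlen, cap = 2e5) {
  n <- mol$n_atoms
  nb <- lapply(seq_len(n), function(i) integer(0))
  for (i in seq_len(mol$n_bonds)) {
    a <- mol$bonds$a1[i]; b <- mol$bonds$a2[i]
    nb[[a]] <- c(nb[[a]], b); nb[[b]] <- c(nb[[b]], a)
  }
  out <- vector("list", maxlen)
  for (k in seq_len(maxlen)) out[[k]] <- list()
  count <- 0L
  dfs <- function(path) {
    last <- path[length(path)]
    for (nx in nb[[last]]) {
      if (nx %in% path) next
      p2 <- c(path, nx)
      len <- length(p2) - 1L
      if (p2[1L] < nx) {  # dedupe reversed copies
        out[[len]][[length(out[[len]]) + 1L]] <<- p2
        count <<- count + 1L
        if (count > cap) stop("path enumeration cap exceeded (molecule too large)")
      }
      if (len < maxlen) dfs(p2)
    }
  }
  for (s in seq_len(n)) dfs(s)
  out
}

# explicit-hydrogen expansion: atoms (element, charge, parent heavy index),
# bond list (i, j, order) over the expanded indexing
expand_hydrogens <- function(mol) {
  n <- mol$n_atoms
  el <- mol$atoms$element
  ch <- mol$atoms$charge
  parent <- seq_len(n)
  bonds <- mol$bonds[, c("a1", "a2", "order"), drop = FALSE]
  idx <- n
  extra <- list()
  for (i in seq_len(n)) {
    for (h in seq_len(mol$atoms$nH[i])) {
      idx <- idx + 1L
      el <- c(el, "H"); ch <- c(ch, 0L); parent <- c(parent, i)
      extra[[length(extra) + 1L]] <- c(i, idx, 1L)
    }
  }
  if (length(extra)) {
    eb <- do.call(rbind, extra)
    bonds <- rbind(bonds, data.frame(a1 = eb[, 1L], a2 = eb[, 2L], order = eb[, 3L]))
  }
  list(element = el, charge = ch, parent = parent, bonds = bonds,
       n = length(el), n_heavy = n)
}

#' Gasteiger-style partial charges
#'
#' Iterative partial equalization of orbital electronegativity (PEOE) with
#' damped charge transfer across bonds, computed on the explicit-hydrogen
#' graph. Electronegativity parameters are bundled per element and
#' hybridization.
#'
#' @param mol a `mol_graph`.
#' @param iterations number of damped iterations.
#' @return List with `heavy` (charges of heavy atoms), `hydrogen` (charges of
#'   the attached hydrogens) and `all` (the full expanded vector).
#' @export
gasteiger_charges <- function(mol, iterations = 6L) {
  ex <- expand_hydrogens(mol)
  hyb <- hybridization(mol)
  par_tab <- function(elem, hy) {
    key <- paste0(elem, if (elem %in% c("C", "N", "O")) paste0(".", hy) else "")
    p <- PEOE_PARAMS[[key]]
    if (is.null(p)) p <- PEOE_PARAMS[["C.sp3"]]
    p
  }
  P <- t(vapply(seq_len(ex$n), function(i) {
    if (ex$element[i] == "H") PEOE_PARAMS[["H"]]
    else par_tab(ex$element[i], hyb[i])
  }, numeric(3L)))
  q <- as.numeric(ex$charge)  # formal charges seed the iteration
  chi_plus <- rowSums(P)      # cation electronegativity a + b + c
  chi_plus[ex$element == "H"] <- 20.02
  damp <- 1
  for (it in seq_len(iterations)) {
    damp <- damp * 0.5
    chi <- P[, 1L] + P[, 2L] * q + P[, 3L] * q^2
    dq <- numeric(ex$n)
    for (i in seq_len(nrow(ex$bonds))) {
      a <- ex$bonds$a1[i]; b <- ex$bonds$a2[i]
      if (chi[a] == chi[b]) next
      lo <- if (chi[a] < chi[b]) a else b
      hi <- if (lo == a) b else a
      t <- (chi[hi] - chi[lo]) / chi_plus[lo] * damp
      dq[lo] <- dq[lo] + t
      dq[hi] <- dq[hi] - t
    }
    q <- q + dq
  }
  list(heavy = q[seq_len(ex$n_heavy)],
       hydrogen = q[-seq_len(ex$n_heavy)],
       all = q, parent = ex$parent, element = ex$element)
}

# PEOE parameters (a, b, c) by element (and hybridization where it matters)
PEOE_PARAMS <- list(
  H       = c(7.17, 6.24, -0.56),
  C.sp3   = c(7.98, 9.18, 1.88),
  C.sp2   = c(8.79, 9.32, 1.51),
  C.sp    = c(10.39, 9.45, 0.73),
  N.sp3   = c(11.54, 10.82, 1.36),
  N.sp2   = c(12.87, 11.15, 0.85),
  N.sp    = c(15.68, 11.70, -0.27),
  O.sp3   = c(14.18, 12.92, 1.39),
  O.sp2   = c(17.07, 13.79, 0.47),
  O.sp    = c(17.07, 13.79, 0.47),
  F       = c(14.66, 13.85, 2.31),
  Cl      = c(11.00, 9.69, 1.35),
  Br      = c(10.08, 8.47, 1.16),
  I       = c(9.90, 7.96, 0.96),
  S       = c(10.14, 9.13, 1.38),
  P       = c(8.90, 8.24, 0.96),
  Si      = c(7.30, 6.57, 0.66),
  B       = c(5.98, 6.82, 0.51)
)
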