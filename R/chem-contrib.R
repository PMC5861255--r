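# Per-atom contribution schemes: octanol/water partition (logP) and molar
# refractivity increments, topological polar surface area, and an
# approximate per-atom accessible surface (Labute-style, from van der Waals
# radii and covalent bond-length estimates). The increment values are this
# package's own calibration (rule-based on element, aromaticity, hydrogen
# count and heteroatom neighborhood), frozen here; they are not the
# Wildman-Crippen set.

# per-heavy-atom logP and MR increments (hydrogens folded into the heavy atom)
atom_contributions <- function(mol) {
  nb <- mol_neighbors(mol)
  n <- mol$n_atoms
  el <- mol$atoms$element
  hyb <- hybridization(mol)
  logp <- numeric(n); mr <- numeric(n)
  for (i in seq_len(n)) {
    e <- el[i]; h <- mol$atoms$nH[i]
    nbr <- if (nrow(nb[[i]])) nb[[i]][, "atom"] else integer(0)
    n_het <- sum(el[nbr] %in% c("N", "O", "S", "P", "F", "Cl", "Br", "I"))
    has_dbl_o <- any(el[nbr] == "O" & nb[[i]][, "order"] == 2)
    lp <- switch(e,
      C = if (mol$atoms$aromatic[i]) 0.29
          else if (has_dbl_o) -0.03
          else if (n_het >= 2) -0.12
          else if (n_het == 1) 0.00
          else 0.14 + 0.03 * h,
      N = if (mol$atoms$aromatic[i]) -0.35
          else if (h >= 2) -0.60 else if (h == 1) -0.50 else -0.30,
      O = if (mol$atoms$aromatic[i]) -0.10
          else if (hyb[i] == "sp2") -0.12
          else if (h >= 1) -0.45 else -0.35,
      S = 0.25, P = -0.45, F = 0.14, Cl = 0.65, Br = 0.86, I = 1.10,
      Si = 0.20, B = -0.10, Se = 0.30, As = -0.20, 0.00)
    mri <- switch(e,
      C = if (mol$atoms$aromatic[i]) 3.40 else 2.50,
      N = 2.80, O = if (hyb[i] == "sp2") 1.90 else 1.60,
      S = 7.40, P = 7.00, F = 1.00, Cl = 5.90, Br = 8.90, I = 14.00,
      Si = 8.50, B = 3.00, Se = 9.00, As = 9.00, 4.00)
    logp[i] <- lp + if (e == "C") 0 else -0.20 * h   # polar X-H lowers logP
    mr[i] <- mri + 1.03 * h
  }
  list(logp = logp, mr = mr)
}

# topological polar surface area contributions (Ertl-style rules for N, O,
# S and P environments; other elements contribute 0)
tpsa_contributions <- function(mol) {
  nb <- mol_neighbors(mol)
  n <- mol$n_atoms
  el <- mol$atoms$element
  out <- numeric(n)
  for (i in seq_len(n)) {
    e <- el[i]
    if (!e %in% c("N", "O", "S", "P")) next
    h <- mol$atoms$nH[i]
    m <- nb[[i]]
    orders <- if (nrow(m)) m[, "order"] else numeric(0)
    arom <- mol$atoms$aromatic[i]
    ch <- mol$atoms$charge[i]
    ndbl <- sum(orders == 2)
    ntrp <- sum(orders == 3)
    deg <- mol$atoms$degree[i]
    out[i] <- if (e == "N") {
      if (arom) {
        if (h == 0 && ch == 0) 12.89 else if (h >= 1) 15.79 else 4.10
      } else if (ch > 0) {
        if (h == 3) 27.64 else if (h == 2) 16.61 else if (h == 1) 4.44 else 0.00
      } else if (ntrp >= 1) 23.79
      else if (ndbl >= 1) { if (h >= 1) 23.85 else 12.36 }
      else { if (h == 2) 26.02 else if (h == 1) 12.03 else 3.24 }
    } else if (e == "O") {
      if (arom) 13.14
      else if (ch < 0) 23.06
      else if (ndbl >= 1) 17.07
      else if (h >= 1) 20.23
      else 9.23
    } else if (e == "S") {
      if (arom) 28.24
      else if (ndbl >= 1 && deg == 1) 32.09
      else if (h >= 1) 38.80
      else if (deg == 2 && ndbl == 0) 25.30
      else 0.00
    } else {  # P
      if (ndbl >= 1 && deg == 3) 9.81 else 13.59
    }
  }
  out
}

# Labute-style approximate per-atom accessible van der Waals surface area.
# Bond length is estimated from covalent radii (shortened for multiple /
# aromatic bonds); each neighbor (including implicit hydrogens) hides a
# spherical cap of the atom's vdW sphere.
vsa_contributions <- function(mol) {
  nb <- mol_neighbors(mol)
  n <- mol$n_atoms
  el <- mol$atoms$element
  Ri <- element_prop(el, "rvdw", default = 1.7)
  rc <- element_prop(el, "rcov", default = 0.77)
  rH_v <- ELEMENTS["H", "rvdw"]; rH_c <- ELEMENTS["H", "rcov"]
  shrink <- function(order, arom) ifelse(arom == 1, 0.92,
                                          c(1.0, 0.87, 0.78)[order])
  out <- numeric(n)
  for (i in seq_len(n)) {
    area <- 4 * pi * Ri[i]^2
    caps <- 0
    m <- nb[[i]]
    if (nrow(m)) for (k in seq_len(nrow(m))) {
      j <- m[k, "atom"]
      dij <- (rc[i] + rc[j]) * shrink(m[k, "order"], m[k, "aromatic"])
      dij <- min(max(dij, abs(Ri[i] - Ri[j]) + 0.05), Ri[i] + Ri[j] - 0.05)
      # height of the hidden cap on sphere i
      hcap <- Ri[i] - (dij^2 + Ri[i]^2 - Ri[j]^2) / (2 * dij)
      caps <- caps + 2 * pi * Ri[i] * max(hcap, 0)
    }
    if (mol$atoms$nH[i] > 0L) {
      dij <- (rc[i] + rH_c)
      dij <- min(max(dij, abs(Ri[i] - rH_v) + 0.05), Ri[i] + rH_v - 0.05)
      hcap <- Ri[i] - (dij^2 + Ri[i]^2 - rH_v^2) / (2 * dij)
      caps <- caps + mol$atoms$nH[i] * 2 * pi * Ri[i] * max(hcap, 0)
    }
    out[i] <- max(area - caps, 1.0)  # floor: every atom exposes some surface
  }
  out
}
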