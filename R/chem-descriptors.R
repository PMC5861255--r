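# The twelve chemical descriptor groups (fourteen callable families,
# 775 values in total). Every family returns a fixed-length feature_vector
# regardless of molecule content; descriptors undefined on degenerate
# graphs (single atom, no rings, zero variance) are reported as 0.

CHEM_GROUPS <- c(constitution = 30L, topology = 35L, connectivity = 44L,
                 estate = 237L, basak = 21L, burden = 64L, kappa = 7L,
                 autocorrelation_mb = 32L, autocorrelation_moran = 32L,
                 autocorrelation_geary = 32L, charge = 25L, property = 6L,
                 moe = 60L, cats = 150L)

#' Compute one chemical descriptor group
#'
#' Dispatches to one of the fourteen descriptor families. Group dimensions
#' are fixed: constitution 30, topology 35, connectivity 44, estate 237,
#' basak 21, burden 64, kappa 7, each autocorrelation flavour 32, charge 25,
#' property 6, moe 60, cats 150.
#'
#' @param mol a (standardized) `mol_graph`.
#' @param group group name, one of `names(chem_group_sizes())`.
#' @return A [feature_vector()] of the group's fixed length.
#' @export
descriptor_group <- function(mol, group) {
  stopifnot(inherits(mol, "mol_graph"))
  if (!group %in% names(CHEM_GROUPS))
    stop("unknown descriptor group '", group, "'; available: ",
         paste(names(CHEM_GROUPS), collapse = ", "))
  fv <- switch(group,
    constitution = desc_constitution(mol),
    topology = desc_topology(mol),
    connectivity = desc_connectivity(mol),
    estate = desc_estate(mol),
    basak = desc_basak(mol),
    burden = desc_burden(mol),
    kappa = desc_kappa(mol),
    autocorrelation_mb = desc_autocorr(mol, "mb"),
    autocorrelation_moran = desc_autocorr(mol, "moran"),
    autocorrelation_geary = desc_autocorr(mol, "geary"),
    charge = desc_charge(mol),
    property = desc_property(mol),
    moe = desc_moe(mol),
    cats = desc_cats(mol))
  stopifnot(length(fv) == CHEM_GROUPS[[group]])
  fv
}

#' Chemical descriptor group sizes
#'
#' @return Named integer vector of the fixed dimension of each group.
#' @export
chem_group_sizes <- function() CHEM_GROUPS

#' All 775 chemical descriptors
#'
#' Concatenates the fourteen families in fixed order (constitution,
#' topology, connectivity, estate, basak, burden, kappa, the three
#' autocorrelations, charge, property, moe, cats): 775 uniquely named
#' values.
#'
#' @param mol a (standardized) `mol_graph`.
#' @return A [feature_vector()] of length 775.
#' @export
all_descriptors <- function(mol) {
  fv_concat(lapply(names(CHEM_GROUPS), function(g) descriptor_group(mol, g)))
}

# finite-guard: undefined / degenerate values become 0
fin0 <- function(x) ifelse(is.finite(x), x, 0)

# ---- constitution (30) ---------------------------------------------------

desc_constitution <- function(mol) {
  el <- mol$atoms$element
  b <- mol$bonds
  nH <- sum(mol$atoms$nH)
  hal <- c("F", "Cl", "Br", "I")
  het <- !el %in% c("C", "H")
  rot <- rotatable_bonds(mol)
  hbd <- sum(mol$atoms$nH > 0 & el %in% c("N", "O", "S"))
  hba <- sum(el %in% c("N", "O") & mol$atoms$charge <= 0)
  mw <- sum(element_prop(el, "mass", 12)) + nH * ELEMENTS["H", "mass"]
  paths <- mol_paths(mol, 6L)
  pc <- lengths(paths)
  v <- c(
    natom = mol$n_atoms, nH = nH, nC = sum(el == "C"), nN = sum(el == "N"),
    nO = sum(el == "O"), nS = sum(el == "S"), nP = sum(el == "P"),
    nF = sum(el == "F"), nCl = sum(el == "Cl"), nBr = sum(el == "Br"),
    nI = sum(el == "I"), nhal = sum(el %in% hal), nhet = sum(het),
    nring = length(mol$rings), nrot = rot, nhbd = hbd, nhba = hba,
    nbond = mol$n_bonds,
    nsbond = sum(b$order == 1L & !b$aromatic),
    ndbond = sum(b$order == 2L & !b$aromatic),
    ntbond = sum(b$order == 3L),
    naro = sum(b$aromatic),
    mw = mw, amw = mw / (mol$n_atoms + nH),
    pc1 = pc[1L], pc2 = pc[2L], pc3 = pc[3L], pc4 = pc[4L], pc5 = pc[5L],
    pc6 = pc[6L])
  feature_vector(fin0(v), paste0("const.", names(v)))
}

rotatable_bonds <- function(mol) {
  if (mol$n_bonds == 0L) return(0L)
  deg <- mol$atoms$degree
  sum(mol$bonds$order == 1L & !mol$bonds$in_ring &
      deg[mol$bonds$a1] > 1L & deg[mol$bonds$a2] > 1L)
}

# ---- topology (35) -------------------------------------------------------

desc_topology <- function(mol) {
  n <- mol$n_atoms
  d <- mol$dist
  d[!is.finite(d)] <- 0   # disconnected pairs excluded from sums
  deg <- mol$atoms$degree
  m <- mol$n_bonds
  dv <- valence_delta(mol)
  ut <- upper.tri(d)
  W <- sum(d[ut])
  npairs <- max(n * (n - 1) / 2, 1)
  Ds <- rowSums(d)
  mu <- m - n + igraph::components(mol$graph)$no
  ecc <- if (n > 1L) apply(d, 1L, max) else 0
  # distance-value distribution (k >= 1)
  dk <- d[ut]; dk <- dk[dk > 0]
  nk <- if (length(dk)) table(dk) else integer(0)
  ide <- if (length(dk)) -sum((nk / length(dk)) * log2(nk / length(dk))) else 0
  kv <- as.numeric(names(nk))
  idw <- if (W > 0) W * log2(W) - sum(kv * nk * log2(kv)) else 0
  degtab <- table(deg)
  ivde <- -sum((degtab / n) * log2(degtab / n))
  eltab <- table(mol$atoms$element)
  tiac <- n * log2(n) - sum(eltab * log2(eltab))
  be <- mol$bonds
  J <- if (m > 0 && all(Ds[c(be$a1, be$a2)] > 0))
    m / (mu + 1) * sum(1 / sqrt(Ds[be$a1] * Ds[be$a2])) else 0
  xu <- if (n > 1 && sum(deg * Ds) > 0)
    sqrt(n) * log(sum(deg * Ds^2) / sum(deg * Ds)) else 0
  hw <- (sum(d[ut]) + sum(d[ut]^2)) / 2
  harary <- { dd <- d[ut]; sum(1 / dd[dd > 0]) }
  zm1 <- sum(deg^2); zm2 <- if (m > 0) sum(deg[be$a1] * deg[be$a2]) else 0
  v <- c(
    W = W, AW = W / npairs, J = J, harary = harary,
    schultz = sum(deg * Ds) + zm1,
    gutman = sum(deg[row(d)[ut]] * deg[col(d)[ut]] * d[ut]),
    ZM1 = zm1, ZM2 = zm2,
    MZM1 = sum(1 / pmax(deg, 1)^2),
    MZM2 = if (m > 0) sum(1 / pmax(deg[be$a1] * deg[be$a2], 1)) else 0,
    quad = 3 - 2 * n + zm1 / 2,
    platt = if (m > 0) sum(deg[be$a1] + deg[be$a2] - 2) else 0,
    diameter = max(ecc), radius = if (n > 1) min(ecc) else 0,
    petitjean = if (n > 1 && min(ecc) > 0) (max(ecc) - min(ecc)) / min(ecc) else 0,
    Xu = xu, pol = sum(d[ut] == 3),
    IDE = ide, IDW = idw, IVDE = ivde, TIAC = tiac,
    ECC = sum(deg * ecc), meanecc = mean(ecc), hyperW = hw,
    ZM1V = sum(dv^2),
    ZM2V = if (m > 0) sum(dv[be$a1] * dv[be$a2]) else 0,
    logW = log1p(W),
    meandeg = if (n > 0) 2 * m / n else 0,
    maxdeg = if (n > 0) max(deg) else 0,
    density = 2 * m / max(n * (n - 1), 1),
    cyclomatic = mu, nSSSR = length(mol$rings),
    meanDs = mean(Ds), vardeg = if (n > 1) stats::var(deg) else 0,
    zagrebco = coindex_zagreb(deg, d))
  feature_vector(fin0(v), paste0("topo.", names(v)))
}

coindex_zagreb <- function(deg, d) {
  n <- length(deg)
  if (n < 2L) return(0)
  ut <- upper.tri(d)
  nonadj <- ut & d > 1
  sum(outer(deg, deg, "+")[nonadj])
}

# ---- connectivity (44) ---------------------------------------------------

chi_of_paths <- function(paths_k, delta) {
  if (length(paths_k) == 0L) return(0)
  sum(vapply(paths_k, function(p) 1 / sqrt(prod(delta[p])), numeric(1L)))
}

# star subgraphs: central atom with k chosen neighbors
chi_cluster <- function(mol, delta, k) {
  nb <- mol_neighbors(mol)
  total <- 0
  for (i in seq_len(mol$n_atoms)) {
    nbr <- if (nrow(nb[[i]])) nb[[i]][, "atom"] else integer(0)
    if (length(nbr) < k) next
    for (comb in utils::combn(nbr, k, simplify = FALSE))
      total <- total + 1 / sqrt(delta[i] * prod(delta[comb]))
  }
  total
}

# path-cluster order 4: 3-star with one arm extended by one bond
chi_pathcluster4 <- function(mol, delta) {
  nb <- mol_neighbors(mol)
  nbrs <- lapply(seq_len(mol$n_atoms), function(i)
    if (nrow(nb[[i]])) nb[[i]][, "atom"] else integer(0))
  seen <- character(0)
  total <- 0
  for (c0 in seq_len(mol$n_atoms)) {
    if (length(nbrs[[c0]]) < 3L) next
    for (arms in utils::combn(nbrs[[c0]], 3L, simplify = FALSE)) {
      for (arm in arms) {
        for (ext in setdiff(nbrs[[arm]], c(c0, arms))) {
          atoms <- c(c0, arms, ext)
          edges <- rbind(sort(c(c0, arms[1])), sort(c(c0, arms[2])),
                         sort(c(c0, arms[3])), sort(c(arm, ext)))
          sig <- paste(apply(edges[order(edges[, 1], edges[, 2]), ], 1L,
                             paste, collapse = "-"), collapse = ";")
          if (sig %in% seen) next
          seen <- c(seen, sig)
          total <- total + 1 / sqrt(prod(delta[atoms]))
        }
      }
    }
  }
  total
}

chi_chain <- function(mol, delta, size) {
  total <- 0
  for (r in mol$rings) if (length(r) == size)
    total <- total + 1 / sqrt(prod(delta[r]))
  total
}

desc_connectivity <- function(mol) {
  deg <- pmax(mol$atoms$degree, 0L)
  dv <- valence_delta(mol)
  ds <- pmax(deg, 1e-12)      # guard isolated atoms
  dvs <- pmax(dv, 1e-12)
  paths <- mol_paths(mol, 10L)
  chi_simple <- c(sum(1 / sqrt(ds)),
                  vapply(1:10, function(k) chi_of_paths(paths[[k]], ds), numeric(1L)))
  chi_val <- c(sum(1 / sqrt(dvs)),
               vapply(1:10, function(k) chi_of_paths(paths[[k]], dvs), numeric(1L)))
  mchi1 <- if (mol$n_bonds > 0) chi_simple[2L] / mol$n_bonds else 0
  c3c <- chi_cluster(mol, ds, 3L); c4c <- chi_cluster(mol, ds, 4L)
  c4pc <- chi_pathcluster4(mol, ds)
  c3cv <- chi_cluster(mol, dvs, 3L); c4cv <- chi_cluster(mol, dvs, 4L)
  c4pcv <- chi_pathcluster4(mol, dvs)
  ch <- vapply(3:6, function(s) chi_chain(mol, ds, s), numeric(1L))
  chv <- vapply(3:6, function(s) chi_chain(mol, dvs, s), numeric(1L))
  v <- c(stats::setNames(chi_simple, paste0("chi", 0:10)),
         mchi1 = mchi1,
         chi3c = c3c, chi4c = c4c, chi4pc = c4pc,
         stats::setNames(ch, paste0("chi", 3:6, "ch")),
         knotp = c3c - c4pc,
         stats::setNames(chi_val, paste0("chiv", 0:10)),
         chiv3c = c3cv, chiv4c = c4cv, chiv4pc = c4pcv,
         stats::setNames(chv, paste0("chiv", 3:6, "ch")),
         knotpv = c3cv - c4pcv,
         stats::setNames(abs(chi_simple[1:5] - chi_val[1:5]),
                         paste0("dchi", 0:4)))
  feature_vector(fin0(v), paste0("conn.", names(v)))
}

# ---- kappa (7) -----------------------------------------------------------

desc_kappa <- function(mol) {
  A <- mol$n_atoms
  paths <- mol_paths(mol, 3L)
  P1 <- mol$n_bonds; P2 <- length(paths[[2L]]); P3 <- length(paths[[3L]])
  alpha <- sum(element_prop(mol$atoms$element, "rcov", 0.76) / 0.76 - 1)
  k1 <- function(A, P) if (P > 0) A * (A - 1)^2 / P^2 else 0
  k2 <- function(A, P) if (P > 0) (A - 1) * (A - 2)^2 / P^2 else 0
  k3 <- function(A, P) {
    if (P <= 0) return(0)
    if (round(A) %% 2 == 1) (A - 1) * (A - 3)^2 / P^2
    else (A - 3) * (A - 2)^2 / P^2
  }
  v <- c(kappa1 = k1(A, P1), kappa2 = k2(A, P2), kappa3 = k3(A, P3),
         kappa1a = k1(A + alpha, P1 + alpha),
         kappa2a = k2(A + alpha, P2 + alpha),
         kappa3a = k3(A + alpha, P3 + alpha))
  phi <- if (A > 0) v["kappa1a"] * v["kappa2a"] / A else 0
  v <- c(v, phi = unname(phi))
  feature_vector(fin0(v), paste0("kappa.", names(v)))
}

# ---- basak information indices (21) --------------------------------------

desc_basak <- function(mol) {
  ex <- expand_hydrogens(mol)
  n <- ex$n
  # neighborhood refinement on the hydrogen-filled multigraph
  nbr <- vector("list", n)
  for (i in seq_len(nrow(ex$bonds))) {
    a <- ex$bonds$a1[i]; b <- ex$bonds$a2[i]; o <- ex$bonds$order[i]
    nbr[[a]] <- rbind(nbr[[a]], c(b, o))
    nbr[[b]] <- rbind(nbr[[b]], c(a, o))
  }
  color <- match(ex$element, unique(ex$element))
  ic <- sic <- cic <- numeric(7L)
  for (r in 0:6) {
    if (r > 0) {
      sig <- vapply(seq_len(n), function(i) {
        m <- nbr[[i]]
        if (is.null(m)) return(paste0(color[i], "|"))
        key <- paste(sort(paste0(m[, 2L], ":", color[m[, 1L]])), collapse = ",")
        paste0(color[i], "|", key)
      }, character(1L))
      color <- match(sig, unique(sig))
    }
    p <- table(color) / n
    h <- -sum(p * log2(p))
    ic[r + 1L] <- h
    sic[r + 1L] <- if (n > 1) h / log2(n) else 0
    cic[r + 1L] <- if (n > 1) log2(n) - h else 0
  }
  feature_vector(fin0(c(ic, sic, cic)),
                 c(paste0("basak.IC", 0:6), paste0("basak.SIC", 0:6),
                   paste0("basak.CIC", 0:6)))
}

# ---- burden eigenvalues (64) ---------------------------------------------

BURDEN_WEIGHTS <- c("mass", "en", "rvdw", "polarizability")

desc_burden <- function(mol) {
  n <- mol$n_atoms
  carbon <- ELEMENTS["C", ]
  out <- numeric(0); nms <- character(0)
  for (w in BURDEN_WEIGHTS) {
    p <- element_prop(mol$atoms$element, w, default = carbon[[w]]) / carbon[[w]]
    B <- matrix(0.001, n, n)
    diag(B) <- p
    for (i in seq_len(mol$n_bonds)) {
      a <- mol$bonds$a1[i]; b <- mol$bonds$a2[i]
      off <- if (mol$bonds$aromatic[i]) 0.15 else mol$bonds$order[i] * 0.1
      B[a, b] <- B[b, a] <- off
    }
    ev <- sort(eigen(B, symmetric = TRUE, only.values = TRUE)$values)
    lo <- c(ev, rep(0, 8L))[1:8]
    hi <- c(rev(ev), rep(0, 8L))[1:8]
    out <- c(out, hi, lo)
    nms <- c(nms, paste0("burden.", w, ".high", 1:8),
             paste0("burden.", w, ".low", 1:8))
  }
  feature_vector(fin0(out), nms)
}

# ---- autocorrelation (3 x 32) --------------------------------------------

desc_autocorr <- function(mol, flavor) {
  n <- mol$n_atoms
  d <- mol$dist
  out <- numeric(0); nms <- character(0)
  carbon <- ELEMENTS["C", ]
  for (w in BURDEN_WEIGHTS) {
    p <- element_prop(mol$atoms$element, w, default = carbon[[w]]) / carbon[[w]]
    pbar <- mean(p)
    ss <- sum((p - pbar)^2)
    for (lag in 1:8) {
      pairs <- which(d == lag & upper.tri(d), arr.ind = TRUE)
      np <- nrow(pairs)
      val <- if (np == 0L) 0 else switch(flavor,
        mb = sum(p[pairs[, 1L]] * p[pairs[, 2L]]),
        moran = if (ss == 0) 0 else
          (sum((p[pairs[, 1L]] - pbar) * (p[pairs[, 2L]] - pbar)) / np) /
            (ss / n),
        geary = if (ss == 0 || n < 2) 0 else
          (sum((p[pairs[, 1L]] - p[pairs[, 2L]])^2) / (2 * np)) /
            (ss / (n - 1)))
      out <- c(out, val)
      nms <- c(nms, paste0("ac.", flavor, ".", w, ".d", lag))
    }
  }
  feature_vector(fin0(out), nms)
}

# ---- charge (25) ---------------------------------------------------------

desc_charge <- function(mol) {
  gc <- gasteiger_charges(mol)
  q <- gc$all
  el <- gc$element
  stat <- function(x, f, default = 0) if (length(x)) f(x) else default
  qpos <- q[q > 0]; qneg <- q[q < 0]
  # local dipole index: mean absolute charge difference over bonds
  ex <- expand_hydrogens(mol)
  ldi <- if (nrow(ex$bonds)) mean(abs(q[ex$bonds$a1] - q[ex$bonds$a2])) else 0
  v <- c(
    SPP = stat(q, max) - stat(q, min),
    LDI = ldi,
    Rnc = if (sum(qneg) != 0) stat(qneg, min) / sum(qneg) else 0,
    Rpc = if (sum(qpos) != 0) stat(qpos, max) / sum(qpos) else 0,
    Mac = mean(abs(q)), Tac = sum(abs(q)),
    Mnc = stat(qneg, mean), Tnc = sum(qneg),
    Mpc = stat(qpos, mean), Tpc = sum(qpos),
    Qass = sum(q^2),
    QCmax = stat(q[el == "C"], max), QCmin = stat(q[el == "C"], min),
    QNmax = stat(q[el == "N"], max), QNmin = stat(q[el == "N"], min),
    QOmax = stat(q[el == "O"], max), QOmin = stat(q[el == "O"], min),
    QHmax = stat(q[el == "H"], max), QHmin = stat(q[el == "H"], min),
    Qmax = stat(q, max), Qmin = stat(q, min),
    QCss = sum(q[el == "C"]^2), QNss = sum(q[el == "N"]^2),
    QOss = sum(q[el == "O"]^2), QHss = sum(q[el == "H"]^2))
  feature_vector(fin0(v), paste0("charge.", names(v)))
}

# ---- molecular property (6) ----------------------------------------------

desc_property <- function(mol) {
  contrib <- atom_contributions(mol)
  logp <- sum(contrib$logp)
  mr <- sum(contrib$mr)
  tpsa <- sum(tpsa_contributions(mol))
  nmult <- sum(mol$bonds$order >= 2L) + sum(mol$bonds$aromatic & mol$bonds$order == 1L)
  ui <- log2(1 + nmult)
  # hydrophilic index: hydrophilic (N/O/S-attached) hydrogens vs carbons
  A <- mol$n_atoms
  nhy <- sum(mol$atoms$nH[mol$atoms$element %in% c("N", "O", "S")])
  nc <- sum(mol$atoms$element == "C")
  hy <- if (A > 1)
    ((1 + nhy) * log2(1 + nhy) + nc * (1 / A) * log2(1 / A) +
       sqrt(nhy / A^2)) / log2(1 + A) else 0
  v <- c(logp = logp, logp2 = logp^2, mr = mr, tpsa = tpsa, ui = ui, hy = hy)
  feature_vector(fin0(v), paste0("prop.", names(v)))
}

# ---- MOE-type surface descriptors (60) -----------------------------------

SLOGP_BINS <- c(-0.4, -0.2, 0, 0.1, 0.15, 0.2, 0.25, 0.3, 0.4, 0.5, 0.6)
SMR_BINS <- c(1.29, 1.82, 2.24, 2.45, 2.75, 3.05, 3.63, 3.8, 4.0)
PEOE_BINS <- c(-0.30, -0.25, -0.20, -0.15, -0.10, -0.05, 0,
               0.05, 0.10, 0.15, 0.20, 0.25, 0.30)
ESTATE_BINS <- c(-0.39, 0.29, 0.717, 1.165, 1.54, 1.807, 2.05, 4.69, 9.17, 15.0)
VSA_BINS <- c(4.78, 5.0, 5.41, 5.74, 6.0, 6.07, 6.45, 7.0, 11.0, 16.0)

bin_sum <- function(weight, key, edges) {
  idx <- findInterval(key, edges) + 1L
  vapply(seq_len(length(edges) + 1L), function(b) sum(weight[idx == b]),
         numeric(1L))
}

desc_moe <- function(mol) {
  vsa <- vsa_contributions(mol)
  contrib <- atom_contributions(mol)
  es <- estate_indices(mol)$S
  gq <- gasteiger_charges(mol)$heavy
  v <- c(
    labuteASA = sum(vsa),
    tpsa = sum(tpsa_contributions(mol)),
    stats::setNames(bin_sum(vsa, contrib$logp, SLOGP_BINS),
                    paste0("slogpVSA", 0:11)),
    stats::setNames(bin_sum(vsa, contrib$mr, SMR_BINS),
                    paste0("smrVSA", 0:9)),
    stats::setNames(bin_sum(vsa, gq, PEOE_BINS),
                    paste0("peoeVSA", 0:13)),
    stats::setNames(bin_sum(vsa, es, ESTATE_BINS),
                    paste0("estateVSA", 0:10)),
    stats::setNames(bin_sum(es, vsa, VSA_BINS),
                    paste0("VSAestate", 0:10)))
  feature_vector(fin0(v), paste0("moe.", names(v)))
}

# ---- E-state group (237) -------------------------------------------------

desc_estate <- function(mol) {
  es <- estate_indices(mol)
  out <- numeric(0)
  for (stat_name in c("sum", "max", "min")) {
    f <- switch(stat_name, sum = sum, max = max, min = min)
    out <- c(out, vapply(ESTATE_TYPES, function(ty) {
      x <- es$S[es$type == ty]
      if (length(x)) f(x) else 0
    }, numeric(1L)))
  }
  feature_vector(fin0(out),
                 paste0("estate.", rep(c("sum", "max", "min"), each = 79L),
                        ".", rep(ESTATE_TYPES, 3L)))
}

# ---- CATS pharmacophore pairs (150) --------------------------------------

PHARM_TYPES <- c("D", "A", "P", "N", "L")

pharmacophore_types <- function(mol) {
  nb <- mol_neighbors(mol)
  el <- mol$atoms$element
  n <- mol$n_atoms
  types <- vector("list", n)
  for (i in seq_len(n)) {
    t <- character(0)
    nbr <- if (nrow(nb[[i]])) nb[[i]][, "atom"] else integer(0)
    has_acidic_env <- any(vapply(nbr, function(j) {
      # O/S neighbor double-bonded to something (C=O, S=O): acidic OH pattern
      m <- nb[[j]]
      nrow(m) > 0 && any(m[, "order"] == 2)
    }, logical(1L)))
    if (el[i] %in% c("N", "O") && mol$atoms$nH[i] > 0L) t <- c(t, "D")
    if (el[i] %in% c("N", "O") && mol$atoms$charge[i] <= 0L) t <- c(t, "A")
    if (mol$atoms$charge[i] > 0L) t <- c(t, "P")
    if (mol$atoms$charge[i] < 0L ||
        (el[i] == "O" && mol$atoms$nH[i] > 0L && has_acidic_env)) t <- c(t, "N")
    if (el[i] %in% c("Cl", "Br", "I", "S") ||
        (el[i] == "C" && !any(el[nbr] %in% c("N", "O")))) t <- c(t, "L")
    types[[i]] <- unique(t)
  }
  types
}

desc_cats <- function(mol) {
  types <- pharmacophore_types(mol)
  d <- mol$dist
  pairs <- utils::combn(PHARM_TYPES, 2L, simplify = FALSE)
  pairs <- c(lapply(PHARM_TYPES, function(x) c(x, x)), pairs)
  # order: DD AA PP NN LL, then DA DP DN DL AP AN AL PN PL NL
  counts <- matrix(0, nrow = length(pairs), ncol = 10L)
  for (i in seq_len(mol$n_atoms)) {
    for (j in i:mol$n_atoms) {
      dij <- if (i == j) 0 else d[i, j]
      if (!is.finite(dij) || dij > 9) next
      for (pi in seq_along(pairs)) {
        t1 <- pairs[[pi]][1L]; t2 <- pairs[[pi]][2L]
        hit <- if (i == j) {
          t1 != t2 && t1 %in% types[[i]] && t2 %in% types[[i]]
        } else {
          (t1 %in% types[[i]] && t2 %in% types[[j]]) ||
          (t2 %in% types[[i]] && t1 %in% types[[j]])
        }
        if (hit) counts[pi, dij + 1L] <- counts[pi, dij + 1L] + 1L
      }
    }
  }
  nms <- as.vector(t(outer(vapply(pairs, paste, character(1L), collapse = ""),
                           0:9, function(p, k) paste0("cats.", p, ".d", k))))
  feature_vector(fin0(as.vector(t(counts))), nms)
}
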