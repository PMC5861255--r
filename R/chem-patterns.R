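# Substructure pattern engine: a small linear-chain pattern language matched
# by the package's own subgraph matcher, plus structural-key primitives
# (element counts, ring properties, degree and hydrogen-count tests).
# Key-set membership is package-defined (frozen enumerations / bundled
# synthetic tables); lengths are pinned to the printed registry sizes.
#
# Chain pattern syntax (linear chains only):
#   atoms:  element symbol (C, N, O, Cl, ...)  any aromaticity
#           lowercase c, n, o, s               aromatic atom
#           A  any heavy atom;  X  halogen;  Q  heteroatom (non-carbon)
#   bonds:  -  single (non-aromatic)   =  double   #  triple
#           :  aromatic                ~  any

parse_chain_pattern <- function(pattern) {
  toks <- regmatches(pattern,
    gregexpr("Cl|Br|Si|Se|As|[BCNOPSFI]|[cnos]|[AXQ]|[-=#:~]", pattern))[[1L]]
  if (paste(toks, collapse = "") != pattern)
    stop("unparseable chain pattern: ", pattern)
  atoms <- toks[seq(1L, length(toks), by = 2L)]
  bonds <- if (length(toks) > 1L) toks[seq(2L, length(toks), by = 2L)] else character(0)
  if (length(atoms) != length(bonds) + 1L)
    stop("malformed chain pattern: ", pattern)
  list(atoms = atoms, bonds = bonds)
}

atom_matches <- function(mol, i, tok) {
  el <- mol$atoms$element[i]
  switch(tok,
    A = TRUE,
    X = el %in% c("F", "Cl", "Br", "I"),
    Q = el != "C",
    c = , n = , o = , s =
      mol$atoms$aromatic[i] && el == toupper(tok),
    el == tok)
}

bond_matches <- function(order, aromatic, tok) {
  switch(tok,
    "~" = TRUE,
    ":" = aromatic,
    "-" = !aromatic && order == 1L,
    "=" = !aromatic && order == 2L,
    "#" = order == 3L)
}

# count embeddings of a linear chain pattern (each undirected embedding
# counted from both ends; presence semantics are unaffected)
match_chain <- function(mol, pattern) {
  p <- parse_chain_pattern(pattern)
  k <- length(p$atoms)
  nb <- mol_neighbors(mol)
  count <- 0L
  extend <- function(path, pos) {
    if (pos > k) { count <<- count + 1L; return(invisible()) }
    last <- path[length(path)]
    m <- nb[[last]]
    if (nrow(m) == 0L) return(invisible())
    for (r in seq_len(nrow(m))) {
      j <- m[r, "atom"]
      if (j %in% path) next
      if (!bond_matches(m[r, "order"], m[r, "aromatic"] == 1, p$bonds[pos - 1L])) next
      if (!atom_matches(mol, j, p$atoms[pos])) next
      extend(c(path, j), pos + 1L)
    }
  }
  for (i in seq_len(mol$n_atoms)) {
    if (atom_matches(mol, i, p$atoms[1L])) {
      if (k == 1L) count <- count + 1L else extend(i, 2L)
    }
  }
  count
}

# ---- structural-key primitives ------------------------------------------

ring_profile <- function(mol) {
  lapply(mol$rings, function(r) {
    el <- mol$atoms$element[r]
    k <- length(r)
    arom <- all(mol$atoms$aromatic[r])
    # saturated: no multiple bond between consecutive ring atoms
    sat <- !arom && !any(vapply(seq_len(k), function(j) {
      a <- r[j]; b <- r[if (j == k) 1L else j + 1L]
      any((mol$bonds$a1 == a & mol$bonds$a2 == b |
           mol$bonds$a1 == b & mol$bonds$a2 == a) & mol$bonds$order >= 2L)
    }, logical(1L)))
    list(size = k, carbon_only = all(el == "C"), hetero = any(el != "C"),
         aromatic = arom, saturated = sat,
         hasN = any(el == "N"), hasO = any(el == "O"))
  })
}

# evaluate one key row (kind + args) against a molecule; returns a count
eval_key <- function(mol, kind, arg1, arg2, rings = ring_profile(mol)) {
  el <- mol$atoms$element
  n1 <- suppressWarnings(as.numeric(arg2))
  switch(kind,
    element = sum(el == arg1),
    hydrogen_total = sum(mol$atoms$nH),
    halogen = sum(el %in% c("F", "Cl", "Br", "I")),
    hetero = sum(!el %in% "C"),
    chain = match_chain(mol, arg1),
    hcount = sum(el == arg1 & mol$atoms$nH >= n1),
    degree = sum(el == arg1 & mol$atoms$degree >= n1),
    charge_pos = sum(mol$atoms$charge > 0),
    charge_neg = sum(mol$atoms$charge < 0),
    ringsize = sum(vapply(rings, function(r) r$size == n1, logical(1L))),
    ringcount = length(rings),
    aromring = sum(vapply(rings, function(r) r$aromatic, logical(1L))),
    satring = sum(vapply(rings, function(r) r$saturated, logical(1L))),
    carbonring = sum(vapply(rings, function(r)
      r$size == n1 && r$carbon_only, logical(1L))),
    heteroring = sum(vapply(rings, function(r)
      r$size == n1 && r$hetero, logical(1L))),
    aromring_size = sum(vapply(rings, function(r)
      r$size == n1 && r$aromatic, logical(1L))),
    satring_size = sum(vapply(rings, function(r)
      r$size == n1 && r$saturated, logical(1L))),
    nring_size = sum(vapply(rings, function(r)
      r$size == n1 && r$hasN, logical(1L))),
    oring_size = sum(vapply(rings, function(r)
      r$size == n1 && r$hasO, logical(1L))),
    stop("unknown key kind: ", kind))
}

# evaluate a key table (columns: kind, arg1, arg2, min) into presence bits
eval_key_table <- function(mol, keys) {
  rings <- ring_profile(mol)
  vapply(seq_len(nrow(keys)), function(i) {
    cnt <- eval_key(mol, keys$kind[i], keys$arg1[i], keys$arg2[i], rings)
    as.integer(cnt >= keys$min[i])
  }, integer(1L))
}

read_key_table <- function(file) {
  path <- system.file("extdata", file, package = "biodesc", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    comment.char = "", quote = "",
                    colClasses = c("integer", "character", "character",
                                   "character", "integer"))
}

# ---- generated key sets (frozen enumerations) ----------------------------

# FP3-style set: 45 single-atom degree keys + 165 bonded-pair keys = 210
fp3_keys <- function() {
  els <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "Si",
           "A", "X", "Q", "c")
  singles <- expand.grid(el = els, deg = 1:3, stringsAsFactors = FALSE)
  rows <- data.frame(kind = "chain", arg1 = NA_character_, arg2 = "",
                     min = 1L, stringsAsFactors = FALSE)[0, ]
  for (i in seq_len(nrow(singles))) {
    pat <- paste(c(singles$el[i], rep(paste0("~", "A"), singles$deg[i])),
                 collapse = "")
    rows <- rbind(rows, data.frame(kind = "chain", arg1 = pat, arg2 = "",
                                   min = 1L, stringsAsFactors = FALSE))
  }
  pels <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "A")
  for (i in seq_along(pels)) for (j in i:length(pels)) for (b in c("-", "=", "#"))
    rows <- rbind(rows, data.frame(kind = "chain",
                                   arg1 = paste0(pels[i], b, pels[j]),
                                   arg2 = "", min = 1L, stringsAsFactors = FALSE))
  stopifnot(nrow(rows) == 210L)
  rows
}

# FP4-style set: 275 single-bonded triples + 32 doubly-bonded triples = 307
fp4_keys <- function() {
  centrals <- c("C", "N", "O", "S", "P")
  flanks <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "A")
  rows <- NULL
  for (ce in centrals) for (i in seq_along(flanks)) for (j in i:length(flanks))
    rows <- rbind(rows, paste0(flanks[i], "-", ce, "-", flanks[j]))
  for (ce in c("C", "N", "S", "P")) for (f2 in c("O", "S", "N", "C"))
    for (f1 in c("C", "N"))
      rows <- rbind(rows, paste0(f1, "-", ce, "=", f2))
  keys <- data.frame(kind = "chain", arg1 = as.vector(rows), arg2 = "",
                     min = 1L, stringsAsFactors = FALSE)
  stopifnot(nrow(keys) == 307L)
  keys
}

# PubChem-style sectioned key set pinned to 881 bits:
# element-count thresholds (115), ring-property thresholds (148),
# bonded-pair presence (94) and enumerated 3-atom chains (524).
pubchem_keys <- function() {
  rows <- list()
  add <- function(kind, arg1 = "", arg2 = "", min = 1L)
    rows[[length(rows) + 1L]] <<- data.frame(kind = kind, arg1 = arg1,
                                             arg2 = arg2, min = min,
                                             stringsAsFactors = FALSE)
  # -- element counts (115)
  for (t in c(4L, 8L, 16L, 32L)) add("hydrogen_total", min = t)
  thr <- list(Li = c(1, 2), Be = 1, B = c(1, 2, 4), C = c(2, 4, 8, 16, 32),
              N = c(1, 2, 4, 8), O = c(1, 2, 4, 8, 16), F = c(1, 2, 4),
              Na = c(1, 2), Mg = 1, Al = 1, Si = c(1, 2), P = c(1, 2, 4),
              S = c(1, 2, 4, 8), Cl = c(1, 2, 4, 8), K = c(1, 2), Ca = 1,
              Br = c(1, 2, 4), I = c(1, 2, 4))
  for (e in names(thr)) for (t in thr[[e]]) add("element", e, min = as.integer(t))
  extra <- c("He", "Ne", "Ar", "Kr", "Xe", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
             "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Rb", "Sr", "Y",
             "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
             "Sb", "Te", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Sm", "Eu", "Gd",
             "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W", "Re",
             "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Th", "U")
  stopifnot(length(extra) == 65L)
  for (e in extra) add("element", e)
  # -- rings (148)
  for (s in 3:10) for (t in 1:5) add("ringsize", arg2 = as.character(s), min = t)
  for (s in 3:10) for (t in 1:2) {
    add("carbonring", arg2 = as.character(s), min = t)
    add("heteroring", arg2 = as.character(s), min = t)
    add("aromring_size", arg2 = as.character(s), min = t)
    add("satring_size", arg2 = as.character(s), min = t)
    add("nring_size", arg2 = as.character(s), min = t)
    add("oring_size", arg2 = as.character(s), min = t)
  }
  for (t in 1:6) add("ringcount", min = t)
  for (t in 1:6) add("aromring", min = t)
  # -- bonded element pairs (94)
  pels <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "Si")
  for (i in seq_along(pels)) for (j in i:length(pels))
    add("chain", paste0(pels[i], "~", pels[j]))
  dbl <- c("C", "N", "O", "S", "P")
  for (i in seq_along(dbl)) for (j in i:length(dbl))
    add("chain", paste0(dbl[i], "=", dbl[j]))
  for (p in list(c("C", "C"), c("C", "N"), c("N", "N")))
    add("chain", paste0(p[1L], "#", p[2L]))
  aro <- c("c", "n", "o", "s")
  for (i in seq_along(aro)) for (j in i:length(aro))
    add("chain", paste0(aro[i], ":", aro[j]))
  # -- enumerated 3-atom chains (fills the remainder to 881)
  fl <- as.vector(outer(pels, c("-", "="), paste0))  # flank token + bond
  chains <- character(0)
  for (ce in c("C", "N", "O", "S", "P", "Si")) {
    for (i in seq_along(fl)) for (j in i:length(fl)) {
      a1 <- sub("[-=]$", "", fl[i]); b1 <- sub("^[A-Za-z]+", "", fl[i])
      a2 <- sub("[-=]$", "", fl[j]); b2 <- sub("^[A-Za-z]+", "", fl[j])
      chains <- c(chains, paste0(a1, b1, ce, b2, a2))
    }
  }
  need <- 881L - length(rows)
  stopifnot(need > 0L, length(chains) >= need)
  for (p in chains[seq_len(need)]) add("chain", p)
  keys <- do.call(rbind, rows)
  stopifnot(nrow(keys) == 881L)
  keys
}

# Ghose-Crippen-style atom-environment class counts (110 classes)
ghosecrippen_counts <- function(mol) {
  nb <- mol_neighbors(mol)
  el <- mol$atoms$element
  hyb <- hybridization(mol)
  n <- mol$n_atoms
  het_nbrs <- vapply(seq_len(n), function(i) {
    nbr <- if (nrow(nb[[i]])) nb[[i]][, "atom"] else integer(0)
    sum(!el[nbr] %in% "C")
  }, integer(1L))
  arom_nbr <- vapply(seq_len(n), function(i) {
    nbr <- if (nrow(nb[[i]])) nb[[i]][, "atom"] else integer(0)
    any(mol$atoms$aromatic[nbr])
  }, logical(1L))
  has_dbl <- vapply(seq_len(n), function(i)
    nrow(nb[[i]]) > 0 && any(nb[[i]][, "order"] == 2), logical(1L))
  counts <- integer(0); nms <- character(0)
  addc <- function(name, value) {
    counts <<- c(counts, as.integer(value)); nms <<- c(nms, name)
  }
  chg3 <- function(ch) ifelse(ch < 0, "neg", ifelse(ch > 0, "pos", "neu"))
  for (ar in c(TRUE, FALSE)) for (h in 0:3) for (hh in 0:2)
    addc(sprintf("C.%s.H%d.het%d", if (ar) "ar" else "al", h, hh),
         sum(el == "C" & mol$atoms$aromatic == ar & mol$atoms$nH == h &
             pmin(het_nbrs, 2L) == hh))
  for (ar in c(TRUE, FALSE)) for (h in 0:2) for (cg in c("neg", "neu", "pos"))
    addc(sprintf("N.%s.H%d.%s", if (ar) "ar" else "al", h, cg),
         sum(el == "N" & mol$atoms$aromatic == ar & pmin(mol$atoms$nH, 2L) == h &
             chg3(mol$atoms$charge) == cg))
  for (ar in c(TRUE, FALSE)) for (h in 0:1) for (cg in c("neg", "neu", "pos"))
    addc(sprintf("O.%s.H%d.%s", if (ar) "ar" else "al", h, cg),
         sum(el == "O" & mol$atoms$aromatic == ar & pmin(mol$atoms$nH, 1L) == h &
             chg3(mol$atoms$charge) == cg))
  for (ar in c(TRUE, FALSE)) for (h in 0:1) for (dd in c(TRUE, FALSE))
    addc(sprintf("S.%s.H%d.%s", if (ar) "ar" else "al", h,
                 if (dd) "dbl" else "sgl"),
         sum(el == "S" & mol$atoms$aromatic == ar & pmin(mol$atoms$nH, 1L) == h &
             has_dbl == dd))
  for (dd in c(TRUE, FALSE)) for (hi in c(TRUE, FALSE))
    addc(sprintf("P.%s.%s", if (dd) "dbl" else "sgl",
                 if (hi) "deg4" else "deg3"),
         sum(el == "P" & has_dbl == dd & (mol$atoms$degree >= 4) == hi))
  for (x in c("F", "Cl", "Br", "I")) for (ar in c(TRUE, FALSE))
    addc(sprintf("%s.%s", x, if (ar) "arneighbor" else "alneighbor"),
         sum(el == x & arom_nbr == ar))
  # hydrogen classes by carrier
  hcl <- list(C_plain = el == "C" & het_nbrs == 0L,
              C_het = el == "C" & het_nbrs > 0L,
              N = el == "N", O = el == "O", S = el == "S",
              other = !el %in% c("C", "N", "O", "S"))
  for (nm in names(hcl)) addc(paste0("H.on_", nm), sum(mol$atoms$nH[hcl[[nm]]]))
  for (e in c("B", "Si")) for (h in c(0L, 1L))
    addc(sprintf("%s.H%s", e, if (h == 0L) "0" else "ge1"),
         sum(el == e & (if (h == 0L) mol$atoms$nH == 0L else mol$atoms$nH >= 1L)))
  for (ar in c(TRUE, FALSE)) for (dg in 1:4)
    addc(sprintf("C.%s.deg%d", if (ar) "ar" else "al", dg),
         sum(el == "C" & mol$atoms$aromatic == ar & pmin(mol$atoms$degree, 4L) == dg))
  for (dg in 1:4) addc(sprintf("N.deg%d", dg),
                       sum(el == "N" & pmin(mol$atoms$degree, 4L) == dg))
  for (dg in 1:2) addc(sprintf("O.deg%d", dg),
                       sum(el == "O" & pmin(mol$atoms$degree, 2L) == dg))
  for (e in c("C", "N", "O", "S")) for (ir in c(TRUE, FALSE))
    addc(sprintf("%s.%s", e, if (ir) "ring" else "chain"),
         sum(el == e & mol$atoms$in_ring == ir))
  addc("any.pos", sum(mol$atoms$charge > 0))
  addc("any.neg", sum(mol$atoms$charge < 0))
  addc("C.sp", sum(el == "C" & hyb == "sp"))
  addc("C.sp2.al", sum(el == "C" & hyb == "sp2" & !mol$atoms$aromatic))
  stopifnot(length(counts) == 110L)
  stats::setNames(counts, nms)
}
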