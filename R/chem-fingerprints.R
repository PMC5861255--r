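# The 19 fingerprint families: substructure-key sets (MACCS-style, E-state,
# Ghose-Crippen-style, FP3/FP4-style, PubChem-style), hashed path / pair /
# torsion / circular families, and 2-point / 3-point topological
# pharmacophore signatures. Lengths are pinned per family; computation is
# deterministic.

FP_REGISTRY <- data.frame(
  name = c("maccs", "estate_fp", "ghosecrippen", "fp3", "fp4", "pubchem",
           "daylight", "atompairs", "torsion", "fp2",
           "ecfp2", "ecfp4", "ecfp6", "fcfp2", "fcfp4", "fcfp6",
           "morgan", "pharm2p", "pharm3p"),
  length = c(166L, 79L, 110L, 210L, 307L, 881L,
             2048L, 2048L, 2048L, 1024L,
             1024L, 1024L, 1024L, 1024L, 1024L, 1024L,
             1024L, 135L, 2135L),
  kind = c("bit", "count", "count", "bit", "bit", "bit",
           "bit", "bit", "bit", "bit",
           "bit", "bit", "bit", "bit", "bit", "bit",
           "bit", "count", "count"),
  stringsAsFactors = FALSE)

#' List the fingerprint families
#'
#' @return Data frame with columns `name`, `length` and `kind` (bit or
#'   count) for the 19 available families.
#' @export
list_fingerprint_families <- function() FP_REGISTRY

#' Compute a molecular fingerprint
#'
#' Dispatches to one of the 19 families of [list_fingerprint_families()].
#' Substructure-key families are driven by bundled / enumerated pattern
#' sets matched with the package's subgraph matcher, hashed families by a
#' deterministic polynomial hash of canonical path / environment codes.
#'
#' @param mol a (standardized) `mol_graph`.
#' @param family family name.
#' @return A `fingerprint_vector`: integer vector of the family's pinned
#'   length with `family` and `kind` attributes.
#' @export
fingerprint <- function(mol, family) {
  stopifnot(inherits(mol, "mol_graph"))
  reg <- FP_REGISTRY
  if (!family %in% reg$name)
    stop("unknown fingerprint family '", family, "'; available: ",
         paste(reg$name, collapse = ", "))
  v <- switch(family,
    maccs = eval_key_table(mol, maccs_table()),
    estate_fp = {
      ty <- estate_atom_types(mol)
      as.integer(table(factor(ty, levels = ESTATE_TYPES)))
    },
    ghosecrippen = unname(ghosecrippen_counts(mol)),
    fp3 = eval_key_table(mol, fp3_keys()),
    fp4 = eval_key_table(mol, fp4_keys()),
    pubchem = eval_key_table(mol, pubchem_keys()),
    daylight = path_fingerprint(mol, maxlen = 7L, nbits = 2048L),
    atompairs = atompair_fingerprint(mol, nbits = 2048L),
    torsion = torsion_fingerprint(mol, nbits = 2048L),
    fp2 = path_fingerprint(mol, maxlen = 7L, nbits = 1024L),
    ecfp2 = circular_fingerprint(mol, 1L, 1024L, "ecfp"),
    ecfp4 = circular_fingerprint(mol, 2L, 1024L, "ecfp"),
    ecfp6 = circular_fingerprint(mol, 3L, 1024L, "ecfp"),
    fcfp2 = circular_fingerprint(mol, 1L, 1024L, "fcfp"),
    fcfp4 = circular_fingerprint(mol, 2L, 1024L, "fcfp"),
    fcfp6 = circular_fingerprint(mol, 3L, 1024L, "fcfp"),
    morgan = circular_fingerprint(mol, 2L, 1024L, "morgan"),
    pharm2p = pharm_2point(mol),
    pharm3p = pharm_3point(mol))
  len <- reg$length[reg$name == family]
  stopifnot(length(v) == len)
  structure(as.integer(v), family = family,
            kind = reg$kind[reg$name == family], class = "fingerprint_vector")
}

#' @export
print.fingerprint_vector <- function(x, ...) {
  cat("<fingerprint_vector> ", attr(x, "family"), " (", attr(x, "kind"),
      "), length ", length(x), ", ", sum(x > 0), " set positions\n", sep = "")
  invisible(x)
}

maccs_env <- new.env(parent = emptyenv())
maccs_table <- function() {
  if (is.null(maccs_env$tab)) {
    tab <- read_key_table("maccs_keys_synthetic.tsv")
    names(tab) <- c("key", "kind", "arg1", "arg2", "min")
    tab$arg1[is.na(tab$arg1)] <- ""
    tab$arg2[is.na(tab$arg2)] <- ""
    maccs_env$tab <- tab
  }
  maccs_env$tab
}

# deterministic polynomial hash of an integer vector into [0, nbits)
hash_codes <- function(codes, nbits) {
  h <- 5381
  for (x in codes) h <- (h * 33 + x) %% 2147483647
  as.integer(h %% nbits)
}

set_bits <- function(idx, nbits) {
  v <- integer(nbits)
  v[unique(idx) + 1L] <- 1L
  v
}

atom_code <- function(mol) {
  z <- as.integer(element_prop(mol$atoms$element, "Z", 0))
  z * 1000L + mol$atoms$degree * 100L + mol$atoms$nH * 10L +
    as.integer(mol$atoms$aromatic)
}

bond_code <- function(order, aromatic) ifelse(aromatic, 4L, order)

# linear-path fingerprint (daylight-style / FP2-style)
path_fingerprint <- function(mol, maxlen, nbits) {
  ac <- as.integer(element_prop(mol$atoms$element, "Z", 0))
  paths <- mol_paths(mol, maxlen)
  bkey <- bond_lookup(mol)
  idx <- integer(0)
  # single atoms too
  idx <- c(idx, vapply(ac, function(a) hash_codes(c(1L, a), nbits), integer(1L)))
  for (k in seq_len(maxlen)) {
    for (p in paths[[k]]) {
      bonds <- vapply(seq_len(k), function(j)
        bkey(p[j], p[j + 1L]), integer(1L))
      fwd <- as.integer(rbind(ac[p], c(bonds, 0L)))
      rev_ <- as.integer(rbind(ac[rev(p)], c(rev(bonds), 0L)))
      canon <- if (paste(fwd, collapse = ",") <= paste(rev_, collapse = ","))
        fwd else rev_
      idx <- c(idx, hash_codes(c(2L, canon), nbits))
    }
  }
  set_bits(idx, nbits)
}

# closure mapping an atom pair to its bond code
bond_lookup <- function(mol) {
  key <- paste(pmin(mol$bonds$a1, mol$bonds$a2),
               pmax(mol$bonds$a1, mol$bonds$a2))
  codes <- bond_code(mol$bonds$order, mol$bonds$aromatic)
  function(a, b) {
    i <- match(paste(min(a, b), max(a, b)), key)
    if (is.na(i)) 0L else as.integer(codes[i])
  }
}

atompair_fingerprint <- function(mol, nbits) {
  n <- mol$n_atoms
  if (n < 2L) return(set_bits(hash_codes(atom_code(mol), nbits), nbits))
  ac <- atom_code(mol)
  idx <- integer(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- mol$dist[i, j]
    if (!is.finite(d)) next
    pr <- sort(c(ac[i], ac[j]))
    idx <- c(idx, hash_codes(c(3L, pr, as.integer(d)), nbits))
  }
  set_bits(idx, nbits)
}

torsion_fingerprint <- function(mol, nbits) {
  paths <- mol_paths(mol, 3L)
  ac <- atom_code(mol)
  idx <- integer(0)
  for (p in paths[[3L]]) {
    fwd <- ac[p]; rev_ <- ac[rev(p)]
    canon <- if (paste(fwd, collapse = ",") <= paste(rev_, collapse = ","))
      fwd else rev_
    idx <- c(idx, hash_codes(c(4L, canon), nbits))
  }
  if (length(idx) == 0L) idx <- hash_codes(c(4L, ac), nbits)
  set_bits(idx, nbits)
}

# ECFP/FCFP/Morgan-style iterated circular environments
circular_fingerprint <- function(mol, radius, nbits, flavor) {
  n <- mol$n_atoms
  init <- switch(flavor,
    ecfp = atom_code(mol) + mol$atoms$charge * 7L,
    morgan = as.integer(element_prop(mol$atoms$element, "Z", 0)) * 10L +
      mol$atoms$degree,
    fcfp = {
      ty <- pharmacophore_types(mol)
      vapply(seq_len(n), function(i) {
        bits <- c("D", "A", "P", "N", "L") %in% ty[[i]]
        as.integer(sum(c(1L, 2L, 4L, 8L, 16L) * bits)) +
          32L * as.integer(mol$atoms$aromatic[i])
      }, integer(1L))
    })
  nb <- mol_neighbors(mol)
  codes <- as.integer(init)
  all_codes <- codes
  for (r in seq_len(radius)) {
    new_codes <- vapply(seq_len(n), function(i) {
      m <- nb[[i]]
      if (nrow(m) == 0L) return(hash_codes(c(5L, r, codes[i]), 2147483646L))
      env <- sort(bond_code(m[, "order"], m[, "aromatic"] == 1) * 1e7 +
                    codes[m[, "atom"]])
      hash_codes(c(5L, r, codes[i], as.integer(env %% 2147483647)), 2147483646L)
    }, integer(1L))
    codes <- new_codes
    all_codes <- c(all_codes, codes)
  }
  set_bits(vapply(all_codes, function(cd) hash_codes(cd, nbits), integer(1L)),
           nbits)
}

# ---- topological pharmacophore signatures --------------------------------

# 2-point: 15 unordered type pairs x distance bins 1..9 = 135 counts
pharm_2point <- function(mol) {
  types <- pharmacophore_types(mol)
  pairs <- c(lapply(PHARM_TYPES, function(x) c(x, x)),
             utils::combn(PHARM_TYPES, 2L, simplify = FALSE))
  counts <- matrix(0L, nrow = 15L, ncol = 9L)
  n <- mol$n_atoms
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- mol$dist[i, j]
    if (!is.finite(d) || d < 1 || d > 9) next
    for (pi in seq_along(pairs)) {
      t1 <- pairs[[pi]][1L]; t2 <- pairs[[pi]][2L]
      if ((t1 %in% types[[i]] && t2 %in% types[[j]]) ||
          (t2 %in% types[[i]] && t1 %in% types[[j]]))
        counts[pi, d] <- counts[pi, d] + 1L
    }
  }
  as.vector(t(counts))
}

# sorted triangle distance classes over bins 1..7 (triangle-valid, minus the
# fully bonded (1,1,1) triangle): 61 classes
pharm_triangle_classes <- function() {
  cls <- list()
  for (a in 1:7) for (b in a:7) for (cc in b:7)
    if (cc <= a + b && !(a == 1 && b == 1 && cc == 1))
      cls[[length(cls) + 1L]] <- c(a, b, cc)
  stopifnot(length(cls) == 61L)
  cls
}

# 3-point: 35 type multisets x 61 triangle classes = 2135 counts
pharm_3point <- function(mol) {
  types <- pharmacophore_types(mol)
  tri_types <- list()
  for (i in seq_along(PHARM_TYPES)) for (j in i:length(PHARM_TYPES))
    for (k in j:length(PHARM_TYPES))
      tri_types[[length(tri_types) + 1L]] <-
        c(PHARM_TYPES[i], PHARM_TYPES[j], PHARM_TYPES[k])
  stopifnot(length(tri_types) == 35L)
  tri_cls <- pharm_triangle_classes()
  cls_key <- vapply(tri_cls, paste, character(1L), collapse = "-")
  counts <- matrix(0L, nrow = 35L, ncol = 61L)
  n <- mol$n_atoms
  typed <- which(lengths(types) > 0L)
  if (length(typed) >= 3L) {
    combs <- utils::combn(typed, 3L, simplify = FALSE)
    for (tr in combs) {
      d3 <- sort(c(mol$dist[tr[1L], tr[2L]], mol$dist[tr[1L], tr[3L]],
                   mol$dist[tr[2L], tr[3L]]))
      if (!all(is.finite(d3)) || d3[1L] < 1 || d3[3L] > 7) next
      ci <- match(paste(d3, collapse = "-"), cls_key)
      if (is.na(ci)) next
      # every distinct type assignment over the three atoms
      for (ti in seq_along(tri_types)) {
        tt <- tri_types[[ti]]
        hit <- any(vapply(list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                               c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)),
                          function(perm)
                            tt[1L] %in% types[[tr[perm[1L]]]] &&
                            tt[2L] %in% types[[tr[perm[2L]]]] &&
                            tt[3L] %in% types[[tr[perm[3L]]]],
                          logical(1L)))
        if (hit) counts[ti, ci] <- counts[ti, ci] + 1L
      }
    }
  }
  as.vector(t(counts))
}
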