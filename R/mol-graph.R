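# Hydrogen-suppressed molecular graph parsed from SMILES / MOL / SDF / InChI.
#
# Format conversion and sanitization are delegated to OpenBabel (ChemmineOB);
# everything computed on top of the resulting V2000 molfile -- implicit
# hydrogen counts, ring perception, aromaticity, topological distances --
# is implemented here.

#' Parse a chemical structure into a molecular graph
#'
#' Converts the input to a V2000 molfile via OpenBabel and builds a
#' hydrogen-suppressed atom/bond graph with implicit hydrogen counts,
#' perceived rings (smallest set of smallest rings) and aromaticity, and a
#' topological distance matrix. For multi-record SDF input the first record
#' is returned; use [parse_structures()] for all records.
#'
#' @param text structure text: a SMILES or InChI string, or MOL/SDF content.
#' @param format one of `"smiles"`, `"mol"`, `"sdf"`, `"inchi"`.
#' @return A `mol_graph` object: list with `atoms` (element, charge, nH,
#'   aromatic, degree, in_ring), `bonds` (a1, a2, order, aromatic, in_ring),
#'   `rings`, `dist` (topological distances) and `title`.
#' @export
#' @examples
#' m <- parse_structure("CCO", "smiles")
#' m$n_atoms  # 3 heavy atoms
parse_structure <- function(text, format = c("smiles", "mol", "sdf", "inchi")) {
  parse_structures(text, format)[[1L]]
}

#' Parse all records of a structure input
#'
#' @inheritParams parse_structure
#' @return List of `mol_graph` objects (one per SDF record; length 1 for
#'   SMILES/InChI/MOL input).
#' @export
parse_structures <- function(text, format = c("smiles", "mol", "sdf", "inchi")) {
  format <- match.arg(format)
  if (length(text) != 1L || !is.character(text) || !nzchar(trimws(text)))
    stop("empty structure input")
  from <- switch(format, smiles = "SMI", inchi = "INCHI", mol = "MOL", sdf = "SDF")
  sdf <- tryCatch(
    ChemmineOB::convertFormat(from, "SDF", source = ensure_newline(text)),
    error = function(e) stop("cannot parse ", format, " input '",
                             substr(trimws(text), 1L, 60L), "': ",
                             conditionMessage(e)))
  blocks <- split_sdf(sdf)
  if (length(blocks) == 0L)
    stop("cannot parse ", format, " input '", substr(trimws(text), 1L, 60L), "'")
  lapply(blocks, molblock_to_graph)
}

ensure_newline <- function(x) if (endsWith(x, "\n")) x else paste0(x, "\n")

split_sdf <- function(sdf) {
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1L]]
  rec <- cumsum(c(0L, utils::head(lines, -1L) == "$$$$"))
  blocks <- split(lines, rec)
  blocks <- lapply(blocks, function(b) b[b != "$$$$"])
  Filter(function(b) any(grepl("V2000", b, fixed = TRUE)), blocks)
}

molblock_to_graph <- function(lines) {
  counts_i <- which(grepl("V2000", lines, fixed = TRUE))[1L]
  if (is.na(counts_i)) stop("no V2000 counts line in molblock")
  na <- as.integer(substr(lines[counts_i], 1L, 3L))
  nb <- as.integer(substr(lines[counts_i], 4L, 6L))
  title <- if (counts_i >= 4L) trimws(lines[counts_i - 3L]) else ""
  if (is.na(na) || na < 1L) stop("molblock with no atoms")
  atom_lines <- lines[counts_i + seq_len(na)]
  bond_lines <- if (nb > 0L) lines[counts_i + na + seq_len(nb)] else character(0)
  atoms <- data.frame(
    element = trimws(substr(atom_lines, 32L, 34L)),
    charge = 0L,
    x = as.numeric(substr(atom_lines, 1L, 10L)),
    y = as.numeric(substr(atom_lines, 11L, 20L)),
    stringsAsFactors = FALSE)
  bonds <- if (nb > 0L) data.frame(
    a1 = as.integer(substr(bond_lines, 1L, 3L)),
    a2 = as.integer(substr(bond_lines, 4L, 6L)),
    order = as.integer(substr(bond_lines, 7L, 9L))
  ) else data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  # aromatic bond type 4 in query-style files: treat as order 1 + flag later
  bonds$order[bonds$order == 4L] <- 1L
  bonds$order[!bonds$order %in% 1:3] <- 1L
  for (ln in lines[startsWith(lines, "M  CHG")]) {
    n <- as.integer(substr(ln, 7L, 9L))
    for (j in seq_len(n)) {
      off <- 10L + (j - 1L) * 8L
      idx <- as.integer(substr(ln, off, off + 3L))
      chg <- as.integer(substr(ln, off + 4L, off + 7L))
      atoms$charge[idx] <- chg
    }
  }
  if (nrow(bonds) && (any(bonds$a1 > na) || any(bonds$a2 > na)))
    stop("bond endpoint out of range in molblock")
  build_mol(atoms, bonds, title)
}

# (re)derive all graph-level annotation from raw atoms/bonds
build_mol <- function(atoms, bonds, title = "") {
  # fold explicit hydrogens into heavy-atom nH counts
  hy <- which(atoms$element == "H")
  nH_explicit <- integer(nrow(atoms))
  if (length(hy) > 0L && nrow(atoms) > length(hy)) {
    for (i in seq_len(nrow(bonds))) {
      if (bonds$a1[i] %in% hy && !(bonds$a2[i] %in% hy))
        nH_explicit[bonds$a2[i]] <- nH_explicit[bonds$a2[i]] + 1L
      if (bonds$a2[i] %in% hy && !(bonds$a1[i] %in% hy))
        nH_explicit[bonds$a1[i]] <- nH_explicit[bonds$a1[i]] + 1L
    }
    keep <- setdiff(seq_len(nrow(atoms)), hy)
    remap <- integer(nrow(atoms)); remap[keep] <- seq_along(keep)
    bonds <- bonds[!(bonds$a1 %in% hy | bonds$a2 %in% hy), , drop = FALSE]
    bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
    nH_explicit <- nH_explicit[keep]
    atoms <- atoms[keep, , drop = FALSE]
    rownames(atoms) <- NULL
  }
  n <- nrow(atoms)
  bondsum <- numeric(n); degree <- integer(n)
  for (i in seq_len(nrow(bonds))) {
    bondsum[bonds$a1[i]] <- bondsum[bonds$a1[i]] + bonds$order[i]
    bondsum[bonds$a2[i]] <- bondsum[bonds$a2[i]] + bonds$order[i]
    degree[bonds$a1[i]] <- degree[bonds$a1[i]] + 1L
    degree[bonds$a2[i]] <- degree[bonds$a2[i]] + 1L
  }
  atoms$nH <- pmax(0L, implicit_valence(atoms$element, atoms$charge, bondsum) -
                        as.integer(bondsum)) + nH_explicit
  atoms$degree <- degree
  g <- igraph::graph_from_data_frame(
    d = if (nrow(bonds)) bonds[, c("a1", "a2")] else data.frame(a1 = integer(0), a2 = integer(0)),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  rings <- perceive_sssr(g, n)
  ring_atoms <- unique(unlist(rings))
  atoms$in_ring <- seq_len(n) %in% ring_atoms
  bonds$in_ring <- vapply(seq_len(nrow(bonds)), function(i)
    any(vapply(rings, function(r) both_in_ring(bonds$a1[i], bonds$a2[i], r),
               logical(1L))), logical(1L))
  arom <- perceive_aromaticity(atoms, bonds, rings)
  atoms$aromatic <- arom$atoms
  bonds$aromatic <- arom$bonds
  dist <- igraph::distances(g)
  dimnames(dist) <- NULL
  structure(list(atoms = atoms, bonds = bonds, rings = rings, dist = dist,
                 graph = g, n_atoms = n, n_bonds = nrow(bonds), title = title),
            class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", x$n_atoms, " heavy atoms, ", x$n_bonds, " bonds, ",
      length(x$rings), " rings",
      if (nzchar(x$title)) paste0(" (", x$title, ")"), "\n", sep = "")
  invisible(x)
}

# standard organic valence adjusted for formal charge
implicit_valence <- function(element, charge, bondsum) {
  v <- vapply(seq_along(element), function(i) {
    el <- element[i]; ch <- charge[i]; bs <- bondsum[i]
    base <- switch(el,
      H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
      Cl = 1, Br = 1, I = 1, Se = 2, As = 3, 0)
    if (base == 0) return(0)            # metals and unknowns: no implicit H
    val <- switch(el,
      C = base - abs(ch),
      N = base + ch,
      O = base + ch,
      S = base + ch,
      P = base + ch,
      B = base - abs(ch),
      base - abs(ch))
    # hypervalent S/P: lift to the next standard valence when bonds exceed it
    if (el == "S" && bs > val) val <- if (bs <= 4) 4 else 6
    if (el == "P" && bs > val) val <- 5
    max(0, val)
  }, numeric(1L))
  as.integer(round(v))
}

both_in_ring <- function(a, b, ring) {
  ia <- match(a, ring); ib <- match(b, ring)
  if (is.na(ia) || is.na(ib)) return(FALSE)
  k <- length(ring)
  abs(ia - ib) == 1L || abs(ia - ib) == k - 1L
}

# Smallest-set-of-smallest-rings style perception: for every edge take the
# shortest cycle through it, then greedily keep rings that are independent
# in the GF(2) cycle space, up to the cyclomatic number.
perceive_sssr <- function(g, n) {
  m <- igraph::ecount(g)
  if (m == 0L || n == 0L) return(list())
  comps <- igraph::components(g)$no
  target <- m - n + comps
  if (target <= 0L) return(list())
  el <- igraph::as_edgelist(g, names = FALSE)
  candidates <- list()
  for (e in seq_len(m)) {
    g2 <- igraph::delete_edges(g, e)
    sp <- suppressWarnings(
      igraph::shortest_paths(g2, from = el[e, 1L], to = el[e, 2L])$vpath[[1L]])
    if (length(sp) > 1L) candidates[[length(candidates) + 1L]] <- as.integer(sp)
  }
  if (length(candidates) == 0L) return(list())
  candidates <- candidates[order(lengths(candidates))]
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  all_keys <- edge_key(el[, 1L], el[, 2L])
  ring_vec <- function(r) {
    k <- length(r)
    a <- r; b <- r[c(2:k, 1L)]
    as.integer(all_keys %in% edge_key(a, b))
  }
  basis <- matrix(integer(0), nrow = m, ncol = 0L)
  rings <- list()
  seen <- character(0)
  for (r in candidates) {
    sig <- paste(sort(r), collapse = ",")
    if (sig %in% seen) next
    v <- ring_vec(r)
    red <- v
    if (ncol(basis) > 0L) {
      # GF(2) reduction against the accepted basis
      for (j in seq_len(ncol(basis))) {
        piv <- which(basis[, j] == 1L)[1L]
        if (red[piv] == 1L) red <- (red + basis[, j]) %% 2L
      }
    }
    if (any(red == 1L)) {
      basis <- cbind(basis, red)
      rings[[length(rings) + 1L]] <- r
      seen <- c(seen, sig)
      if (length(rings) == target) break
    }
  }
  rings
}

# Simplified Hueckel rule: a ring is aromatic when every member either has an
# endocyclic double bond (1 pi electron) or is a heteroatom / carbanion
# donating a lone pair (2 pi electrons) and the total is 4n + 2.
perceive_aromaticity <- function(atoms, bonds, rings) {
  n <- nrow(atoms)
  arom_atoms <- logical(n)
  arom_bond_keys <- character(0)
  bkey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  for (ring in rings) {
    k <- length(ring)
    if (!k %in% c(5L, 6L)) next
    pi_e <- integer(k)
    ok <- TRUE
    for (j in seq_len(k)) {
      a <- ring[j]
      nb_prev <- ring[if (j == 1L) k else j - 1L]
      nb_next <- ring[if (j == k) 1L else j + 1L]
      inring_dbl <- any((bonds$a1 == a & bonds$a2 %in% c(nb_prev, nb_next) |
                         bonds$a2 == a & bonds$a1 %in% c(nb_prev, nb_next)) &
                        bonds$order == 2L)
      any_dbl <- any((bonds$a1 == a | bonds$a2 == a) & bonds$order >= 2L)
      el <- atoms$element[a]
      if (inring_dbl) pi_e[j] <- 1L
      else if (!any_dbl && el %in% c("N", "O", "S", "Se", "P")) pi_e[j] <- 2L
      else if (!any_dbl && el == "C" && atoms$charge[a] == -1L) pi_e[j] <- 2L
      else { ok <- FALSE; break }
    }
    if (ok && sum(pi_e) %% 4L == 2L) {
      arom_atoms[ring] <- TRUE
      a <- ring; b <- ring[c(2:k, 1L)]
      arom_bond_keys <- c(arom_bond_keys, bkey(a, b))
    }
  }
  list(atoms = arom_atoms,
       bonds = bkey(bonds$a1, bonds$a2) %in% arom_bond_keys)
}
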