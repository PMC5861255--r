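# Electrotopological state (E-state) indices and atom typing.
#
# Atom types follow the Hall-Kier element/bond-environment scheme: the type
# name encodes the bonds to heavy neighbors (d = double, t = triple,
# a = aromatic, s = single, in that order) plus the element and hydrogen
# count. 78 named types plus one catch-all ("other") give the 79-type
# registry used by both the E-state descriptor group and the E-state
# fingerprint.

ESTATE_TYPES <- c(
  "sLi", "ssBe", "ssssBe", "ssBH", "sssB", "ssssB",
  "sCH3", "dCH2", "ssCH2", "tCH", "dsCH", "aaCH", "sssCH", "ddC", "tsC",
  "dssC", "aasC", "aaaC", "ssssC",
  "sNH3", "sNH2", "ssNH2", "dNH", "ssNH", "aaNH", "tN", "sssNH", "dsN",
  "aaN", "sssN", "ddsN", "aasN", "ssssN",
  "sOH", "dO", "ssO", "aaO", "sF",
  "sSiH3", "ssSiH2", "sssSiH", "ssssSi",
  "sPH2", "ssPH", "sssP", "dsssP", "sssssP",
  "sSH", "dS", "ssS", "aaS", "dssS", "ddssS", "sCl",
  "sGeH3", "ssGeH2", "sssGeH", "ssssGe",
  "sAsH2", "ssAsH", "sssAs", "dsssAs", "sssssAs",
  "sSeH", "dSe", "ssSe", "aaSe", "ddssSe", "sBr",
  "sSnH3", "ssSnH2", "sssSnH", "ssssSn", "sI",
  "sPbH3", "ssPbH2", "sssPbH", "ssssPb",
  "other")

# per-atom E-state type names
estate_atom_types <- function(mol) {
  nb <- mol_neighbors(mol)
  vapply(seq_len(mol$n_atoms), function(i) {
    m <- nb[[i]]
    letters_ <- character(0)
    if (nrow(m) > 0L) {
      letters_ <- ifelse(m[, "aromatic"] == 1, "a",
                         c("s", "d", "t")[m[, "order"]])
    }
    counts <- table(factor(letters_, levels = c("d", "t", "a", "s")))
    bondstr <- paste(rep(names(counts), counts), collapse = "")
    h <- mol$atoms$nH[i]
    hstr <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
    ty <- paste0(bondstr, mol$atoms$element[i], hstr)
    if (ty %in% ESTATE_TYPES) ty else "other"
  }, character(1L))
}

#' E-state indices of a molecule
#'
#' Per-atom electrotopological state values S_i = I_i + sum_j
#' (I_i - I_j) / (d_ij + 1)^2, with intrinsic state
#' I = ((2/n)^2 delta_v + 1) / delta over the hydrogen-suppressed graph
#' (n the principal quantum number, delta_v the valence delta, delta the
#' heavy-atom degree, floored at 1 for isolated atoms).
#'
#' @param mol a `mol_graph`.
#' @return List with `S` (per-atom E-state values), `I` (intrinsic states)
#'   and `type` (per-atom Hall-Kier type names).
#' @export
estate_indices <- function(mol) {
  n <- mol$n_atoms
  dv <- valence_delta(mol)
  delta <- pmax(mol$atoms$degree, 1L)
  pq <- quantum_n(mol$atoms$element)
  I <- ((2 / pq)^2 * dv + 1) / delta
  S <- I
  if (n > 1L) {
    d <- mol$dist
    for (i in seq_len(n)) {
      j <- setdiff(seq_len(n), i)
      fin <- is.finite(d[i, j])
      S[i] <- I[i] + sum((I[i] - I[j][fin]) / (d[i, j][fin] + 1)^2)
    }
  }
  list(S = S, I = I, type = estate_atom_types(mol))
}
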