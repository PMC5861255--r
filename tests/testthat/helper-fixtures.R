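# Shared fixtures: small molecules with hand-checkable structure, and
# seeded random sequences.

fixture_smiles <- c(
  methane = "C", ethane = "CC", ethanol = "CCO", butane = "CCCC",
  isobutane = "CC(C)C", benzene = "c1ccccc1", toluene = "Cc1ccccc1",
  pyridine = "c1ccncc1", phenol = "Oc1ccccc1", furan = "c1ccoc1",
  acetic_acid = "CC(=O)O", acetone = "CC(C)=O", acetonitrile = "CC#N",
  cyclohexane = "C1CCCCC1", aspirin = "CC(=O)Oc1ccccc1C(=O)O",
  caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C", glycine = "NCC(=O)O",
  chlorobenzene = "Clc1ccccc1", dmso = "CS(C)=O", urea = "NC(N)=O")

fixture_mols <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- lapply(fixture_smiles, parse_structure, format = "smiles")
    cache
  }
})

# independent BFS topological distances (test-side oracle helper)
bfs_distances <- function(mol) {
  n <- mol$n_atoms
  adj <- vector("list", n)
  for (i in seq_len(mol$n_bonds)) {
    a <- mol$bonds$a1[i]; b <- mol$bonds$a2[i]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) if (!is.finite(d[s, w])) {
        d[s, w] <- d[s, v] + 1
        queue <- c(queue, w)
      }
    }
  }
  d
}
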