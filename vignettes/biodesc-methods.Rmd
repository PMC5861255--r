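---
title: "Molecular representation with biodesc: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular representation with biodesc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biodesc)
```

## What the package computes

`biodesc` turns three kinds of molecular objects into fixed-length, named
numeric vectors that machine-learning pipelines can consume directly:

* **proteins** (strings over the 20 canonical residues): compositions,
  autocorrelations, CTD, conjoint triads, sequence-order and pseudo
  amino acid composition families;
* **DNA** (strings over ACGT): k-mer compositions, dinucleotide and
  trinucleotide auto/cross covariance, pseudo nucleotide compositions;
* **small molecules** (SMILES, MOL/SDF, InChI): twelve descriptor groups
  totalling 775 values over a hydrogen-suppressed molecular graph, plus
  nineteen fingerprint families;

and, on top of these, **pairwise interaction vectors** built by five
combination strategies (same-type concatenation in both orderings,
elementwise sum/product, tensor product; cross-type concatenation and
tensor product).

## Sequence validation

Validators uppercase their input, strip all whitespace (so wrapped FASTA
is handled), and return the sequence length when every character belongs
to the canonical alphabet, and 0 otherwise. Ambiguity codes (B, Z, X, U,
O), gaps and RNA bases are rejected rather than translated, because every
bundled property table and every descriptor family indexes the canonical
alphabets only; a permissive validator would silently produce undefined
table lookups downstream. Zero-length input also validates to 0 — the
package treats 0 uniformly as "not usable", and no descriptor is defined
on an empty sequence. Positions are 1-based in all documentation (the CTD
distribution family reports "position of the first occurrence / L").

## Protein families

**k-peptide composition** (k = 1, 2, 3; dimensions 20/400/8000) divides
k-mer counts by the number of windows L − k + 1, so each vector sums to
exactly 1.

**Autocorrelation** (Moreau–Broto, Moran, Geary) correlates a per-residue
physicochemical scale P along the chain at lags d = 1..30, with eight
bundled scales (hydrophobicity, average flexibility, polarizability, free
energy of solution, accessible surface area, residue volume, steric
parameter, relative mutability), giving 8 × 30 = 240 values per flavour.
Scales are z-scored over the 20 residues with the *population* standard
deviation before use — this is what "normalized" means here; the raw
scales are bundled alongside and user tables are accepted as two-column
text. A homopolymer has zero sequence variance, which makes Moran and
Geary 0/0; the package reports 0.0 for these degenerate cases rather than
NaN so that downstream matrices stay finite.

**CTD** uses seven fixed three-class partitions of the alphabet
(hydrophobicity, van der Waals volume, polarity, polarizability, charge,
secondary structure, solvent accessibility). Composition is reported as
fractions in [0, 1]; Transition counts unordered class-pair adjacencies
divided by L − 1; Distribution reports, per class, the 1-based positions
of the first, 25%, 50%, 75% and 100% occurrences divided by L and
multiplied by 100 (so values live in [0, 100]; absent classes give 0).
The percentile occurrence is the ⌈q·n⌉-th one (first occurrence for the
0⁺ percentile), which resolves ties deterministically.

**Conjoint triads** map residues to the classic seven electrostatic/volume
classes and count all 7³ = 343 class triads over the L − 2 windows as raw
counts.

**Sequence order**: τ_d = Σ d(R_i, R_{i+d})² for d = 1..30 per distance
matrix. Two matrices are bundled: the Grantham distance, *recomputed* in
code from Grantham's composition/polarity/volume formula (scaled so the
mean over distinct pairs is 100), and a synthetic physicochemical distance
(Euclidean over the z-scored Chou property triple, normalized to maximum
1). The second matrix is a stand-in constructed by this package — it is
*not* the published Schneider–Wrede matrix, which is why its name carries
the `synthetic` label. The quasi-sequence-order vector divides the 20
residue counts and the 30 weighted coupling numbers by the common
denominator Σf + w·Στ with w = 0.1, so each per-matrix block of 50 sums
to 1.

**PseAAC** uses correlation factors θ_j averaging the mean squared
difference of three standardized scales (hydrophobicity, hydrophilicity,
side-chain mass) at lag j; defaults λ = 30, w = 0.05 give 20 + 30 = 50
components summing to 1, all nonnegative. The **amphiphilic** variant
computes one factor per (scale, lag) pair for hydrophobicity and
hydrophilicity separately using mean *products* along the chain
(2λ pseudo components; default λ = 15 gives 50). Because products of
standardized scales can be negative, amphiphilic components can be
negative; the vector still sums to exactly 1 by construction. The weights
w = 0.1 (QSO) and w = 0.05 (PseAAC/APAAC) are the conventional defaults.

`protein_all()` concatenates every family at defaults: 9890 uniquely
named values; it requires L > 30 (the largest default lag) and names the
limiting family in its error message otherwise.

## DNA families

The oligonucleotide property tables bundled under
`extdata/*_synthetic.tsv` have the conventional set sizes — 38
dinucleotide and 12 trinucleotide indices — but their *values are
synthetic* (seeded, frozen at package creation): published experimental
index sets are not redistributable here. They are z-scored over the 4^k
oligonucleotides before use, and users can substitute their own wide
tabular file (an `oligo` column plus one column per index). All printed
dimensions depend only on the set sizes: auto covariance 38 × 2 = 76,
cross covariance 38 × 37 × 2 = 2812 (ordered property pairs — the only
reading that reproduces 2812), auto-cross 2888; trinucleotide 24/264/288
with maxlag 2 throughout.

Pseudo nucleotide compositions use λ = 2 and w = 0.05 by default, giving
16 + 2 = 18 (dinucleotide) and 64 + 2 = 66 (trinucleotide parallel)
components. In series-correlation mode one factor is produced per
(property, lag) pair: 64 + 2·12 = 88 for trinucleotides, and
16 + 2·38 = 92 for dinucleotides — 92, not a round table value, is a
consequence of the 38-index set and is documented rather than adjusted.
Reverse-complement collapsing of 2-mers yields the 10 combinatorial
classes (palindromes map to themselves); only the forward strand is ever
scanned otherwise. `dna_all()` concatenates all families: 6642 values.

## Small molecules

**Parsing and pretreatment.** Format conversion and sanitization are
delegated to OpenBabel (via ChemmineOB); everything on top of the emitted
V2000 molfile is computed in this package: implicit hydrogen counts from
standard valences adjusted for formal charge, ring perception
(smallest-set-of-smallest-rings via shortest cycles through each edge with
GF(2) independence), and a simplified Hückel aromaticity rule — a 5- or
6-ring is aromatic when every member contributes an endocyclic π bond or
a heteroatom lone pair and the total is 4n + 2. This classifies benzene,
pyridine, pyrrole, furan, thiophene and fused systems correctly and
deliberately rejects quinones; exotic mesoionic systems are out of scope.
The ten-step pretreatment pipeline applies, in fixed order: functional
group normalization, charge-pair reconnection (P⁺–O⁻ / S⁺–O⁻ collapse to
double bonds; nitro keeps its charge-separated normal form), metal bond
breaking, deionization, tautomer canonicalization, neutralization,
stereo stripping, largest-fragment (salt/solvent) filtering, insensitive
parent generation, and validation. Tautomer canonicalization and the
insensitive-parent step are documented no-ops: the parser already
canonicalizes per input and the graph model tracks neither isotopes nor
stereocenters. The pipeline is idempotent, and validation attaches flags
(net charge, metals, unparameterized elements) rather than failing.

**Descriptor groups.** The group totals are fixed (30 + 35 + 44 + 237 +
21 + 64 + 7 + 3×32 + 25 + 6 + 60 + 150 = 775) and the membership of each
group is frozen in code: constitution counts atoms/bonds/rings/H-bonding
and paths of length 1–6; topology is 35 distance- and degree-based
indices (Wiener, Balaban J, Harary, Zagreb and variants, Schultz, Gutman,
Platt, eccentricity and information indices); connectivity is the chi
family (simple and valence, path orders 0–10, 3/4-clusters, path-cluster,
3–6 chains, and five simple-valence differences); kappa is the three
shape indices, their α-modified forms and flexibility Φ; Burden gives the
highest/lowest 8 eigenvalues of the Burden matrix under four atomic
weightings (mass, electronegativity, van der Waals radius,
polarizability); the same four weightings drive the three
autocorrelation flavours at lags 1–8. E-state provides sum/max/min of
Hall–Kier S values per atom type over a 79-type registry (78 named
element/bond-environment types plus one catch-all). Charges come from an
iterative damped electronegativity-equalization (PEOE) scheme implemented
on the explicit-hydrogen graph; 25 statistics summarize them. The
property block carries logP, logP², molar refractivity, TPSA (Ertl-style
N/O/S/P rules), an unsaturation index and a hydrophilic index; the
logP/MR increments are this package's own rule-based calibration (element
× aromaticity × hydrogen count × heteroatom neighborhood), not the
Wildman–Crippen table. MOE-type descriptors bin an approximate per-atom
accessible surface (computed from van der Waals radii and covalent
bond-length estimates) by logP, MR, partial charge and E-state value,
with frozen bin edges. CATS counts pharmacophore point pairs
(donor/acceptor/positive/negative/lipophilic) at topological distances
0–9: 15 pairs × 10 bins = 150.

Descriptors undefined on degenerate graphs — a single atom has no bonds,
paths or eigenvalue spread — are reported as 0.0, never NaN, so the 775
slots are always filled.

**Fingerprints.** Nineteen families with pinned lengths. Substructure-key
families (MACCS-style 166, E-state 79, Ghose–Crippen-style 110, FP3-style
210, FP4-style 307, PubChem-style 881) are driven by bundled or
enumerated pattern sets in a small chain-pattern language matched by the
package's own subgraph matcher; because every key tests for the presence
of a substructure or a monotone count threshold, key bits are monotone
under substructure embedding. These key sets reproduce the printed
*lengths* and semantics class (substructure keys), not the bit-for-bit
definitions of the historical sets — the MACCS table ships as
`extdata/maccs_keys_synthetic.tsv` to make that explicit. Hashed families
(Daylight-style paths, atom pairs, topological torsions, FP2, Morgan,
ECFP2/4/6, FCFP2/4/6) hash canonical path or iterated circular
environment codes with a deterministic polynomial hash; FCFP initializes
environments from pharmacophore roles rather than element types. The
2-point pharmacophore signature is 15 type pairs × distance bins 1–9
(135); the 3-point signature is 35 type triples × 61 triangle classes
(sorted distance triples over bins 1–7 satisfying the triangle
inequality, excluding the fully bonded (1,1,1) triangle), 2135 counts.

## Interaction descriptors

For same-type operands of dimension p: concatenation returns *both*
orderings F_ab = (F_a, F_b) and F_ba = (F_b, F_a) (each 2p);
sum/product returns the elementwise sums followed by the elementwise
products (2p, block order chosen over interleaving and documented);
tensor product returns F(k) = F_a(i)·F_b(j) with k = (i−1)·p + j (p²).
For cross-type operands the tensor index is row-major
k = (i−1)·p_d + j — the alternative (i−1)·p_t + j collides whenever
p_t ≠ p_d, so the bijective indexing is used. Output names are prefixed
(`a.`, `b.`, `sum.`, `prod.`, `t.<i>*d.<j>`) to keep global uniqueness.

## Synthetic data and what the tests show

`random_sequences()` draws i.i.d. uniform letters with a local, restored
RNG seed: every call with equal arguments returns identical output.
Uniform sequences exercise every code path (all k-mers, all classes) but
deliberately lack the compositional bias, repeats and homology structure
of real proteins and genomes — passing tests therefore demonstrate
dimensional contracts, formula correctness against brute-force oracles,
and determinism, not biological signal. Test problem sizes (sequences of
length 10–100, molecules up to ~25 heavy atoms, 20–100 property-based
repetitions) keep the whole suite in the minutes range on one CPU.

## Known limitations

* Aromaticity is rule-based (4n + 2 over SSSR rings); charged or
  mesoionic aromatics beyond carbanion rings are perceived as aliphatic.
* logP/MR/TPSA/ASA increments are package calibrations: ranking and
  dimensional behaviour are tested, absolute agreement with other
  toolkits is not promised.
* The DNA property tables and parts of the substructure key sets are
  synthetic stand-ins (named accordingly); swap in measured tables via
  the documented file formats for production use.
* Polymers and organometallics are supported only as far as the
  metal-disconnection pretreatment step; 3D and quantum-chemical
  descriptors are out of scope.
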