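Package: biodesc
Title: Molecular Descriptors for Chemicals, Proteins, DNA and Their Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes structural and physicochemical descriptor vectors for
    small molecules (from SMILES, MOL/SDF or InChI), proteins and DNA (from
    sequences or FASTA), together with pairwise interaction descriptors built
    by concatenation, elementwise sum/product and tensor-product strategies.
    Protein families cover k-peptide compositions, three autocorrelations,
    composition/transition/distribution (CTD), conjoint triads,
    sequence-order-coupling numbers, quasi-sequence-order and two pseudo
    amino acid composition modes. DNA families cover k-mer compositions,
    dinucleotide and trinucleotide auto/cross covariance and pseudo
    nucleotide compositions. Chemical families cover twelve descriptor
    groups (775 values) and nineteen fingerprint types over a
    hydrogen-suppressed molecular graph.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
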