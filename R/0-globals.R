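# Canonical alphabets; fixed ordering used by every descriptor family.
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
DNA_ALPHABET <- c("A", "C", "G", "T")
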