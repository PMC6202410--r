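# Alphabet order used throughout the package: A, C, G, T.
# Complement under the integer coding 1..4 is code -> 5 - code.
DNA_BASES <- c("A", "C", "G", "T")

# All 16 dinucleotides in code order: (first - 1) * 4 + second.
DINUCLEOTIDES <- as.vector(t(outer(DNA_BASES, DNA_BASES, paste0)))
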