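# L14 residue annotations (chain K of the 2AWB 50S subunit numbering).
# mutagenesis: outcome of alanine substitution in the yeast two-hybrid
# interaction assay; bridge: intersubunit-bridge membership from the
# cryo-EM bridge assignments.
K	97	mutagenesis:abolished	A
K	98	mutagenesis:weakened	A
K	114	mutagenesis:abolished	A
K	117	mutagenesis:unaffected	A
K	80	mutagenesis:unaffected	A
K	100	mutagenesis:unaffected	A
K	121	mutagenesis:unaffected	A
K	49	mutagenesis:unaffected	A
K	51	mutagenesis:unaffected	A
K	97	bridge:B8	.
K	98	bridge:B8	.
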