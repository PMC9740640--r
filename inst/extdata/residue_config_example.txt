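# Example residue-table override for residue_table(file = ...).
# One line per residue: <letter> <C> <H> <N> <O> <S> <NEH>
# Entries replace the built-in defaults residue by residue; residues not
# listed keep their defaults.  '#' starts a comment.
#
# Example: alternative exchangeable-hydrogen counts for Ala and Gly.
A 3 5 1 1 0 3.70
G 2 3 1 1 0 2.10
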