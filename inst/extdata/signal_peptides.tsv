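# Signal-peptide lengths (residues) used for mature-protein numbering of
# exon-2 translations.
locus	signal_peptide_len
A	24
B	24
C	24
DQA1	23
DQB1	32
DPA1	31
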