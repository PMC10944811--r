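# table2: non-coding (5'UTR/intron/3'UTR) differences of the full-length
# sequenced alleles against the reference allele of comparison, in genomic
# coordinates (1 = first base of exon 1, 5'UTR negative). Aggregated entries
# ("10 differences", "> 300 differences") are kept as printed in the curated
# record; see table3/table4 style informative-site analyses for details.
allele	compared_to	differences	comment
A*03:182	A*03:01:01:01	I6 C2605T	Not unique for A*03
B*18:34	B*18:01:01:01	I3 T1127C;I5 A2180G;3'UTR T3014C;3'UTR C3358T;3'UTR C3472T;3'UTR C3609T	No differences with B*18:01:01:02
B*53:06	B*53:01:01:01	10 differences	Possible recombination
C*03:04:19	C*03:04:01:01	I3 G1030A	Possible recombination
C*16:201	C*16:01:01:01	5'UTR G-415A	Unique for C*16
DQA1*01:06	DQA1*01:01:01:01	Many differences	Possible recombination
DQA1*04:04	DQA1*04:01:01:01	I1 3205_3206insA	homopolymer
DQB1*03:114	DQB1*03:01:01:01	I1 C744T;I2 G3363A	Not unique for DQB1*03
DQB1*06:03:11	DQB1*06:01:01:01	> 300 differences	No differences with DQB1*06:03:01:01
DQB1*06:73	DQB1*06:01:01:01	> 300 differences	No differences with DQB1*06:02:01:01
DQB1*06:286	DQB1*06:01:01:01	> 300 differences	No differences with DQB1*06:02:01:01
DPA1*01:03:14	DPA1*01:03:01:01	I1 G1723A;I1 C3318G;I2 G4149C	Not unique for DPA1*01
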