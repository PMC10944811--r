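# Canonical HLA gene models: ordered feature lengths (nt) per locus.
# Exon lengths reproduce the coding-nucleotide arithmetic of IPD-IMGT/HLA
# submissions (class I: A 73/270/276/276/117/33/48/5, B 73/270/276/276/117/
# 33/44, C 73/270/276/276/120/33/48/5; class II: DQA1 85/249/279/155,
# DQB1 85/270/282/111/24/14, DPA1 100/246/282/155). Intron/UTR lengths are
# IMGT-scale values consistent with the genomic coordinates used in
# difference reports; reference UTR lengths vary between alleles, so
# non-coding added counts are taken from records, not recomputed from here.
locus	feature	length
A	UTR5	300
A	E1	73
A	I1	130
A	E2	270
A	I2	241
A	E3	276
A	I3	589
A	E4	276
A	I4	102
A	E5	117
A	I5	444
A	E6	33
A	I6	142
A	E7	48
A	I7	168
A	E8	5
A	UTR3	475
B	UTR5	285
B	E1	73
B	I1	130
B	E2	270
B	I2	243
B	E3	276
B	I3	576
B	E4	276
B	I4	102
B	E5	117
B	I5	441
B	E6	33
B	I6	96
B	E7	44
B	UTR3	1122
C	UTR5	500
C	E1	73
C	I1	130
C	E2	270
C	I2	244
C	E3	276
C	I3	589
C	E4	276
C	I4	102
C	E5	120
C	I5	441
C	E6	33
C	I6	96
C	E7	48
C	I7	100
C	E8	5
C	UTR3	1000
DQA1	UTR5	400
DQA1	E1	85
DQA1	I1	3775
DQA1	E2	249
DQA1	I2	570
DQA1	E3	279
DQA1	I3	600
DQA1	E4	155
DQA1	UTR3	700
DQB1	UTR5	150
DQB1	E1	85
DQB1	I1	2800
DQB1	E2	270
DQB1	I2	1200
DQB1	E3	282
DQB1	I3	600
DQB1	E4	111
DQB1	I4	250
DQB1	E5	24
DQB1	I5	150
DQB1	E6	14
DQB1	UTR3	716
DPA1	UTR5	300
DPA1	E1	100
DPA1	I1	3400
DPA1	E2	246
DPA1	I2	1000
DPA1	E3	282
DPA1	I3	400
DPA1	E4	155
DPA1	UTR3	417
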