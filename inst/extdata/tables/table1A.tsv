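# table1A: 19 HLA class I alleles extended to full-length sequence, with the
# EMBL-ENA accession and IPD-IMGT/HLA submission numbers and the numbers of
# coding and non-coding nucleotides added to the database. exons_added lists
# the newly resolved exons (empty when the exon sequences were already known);
# noncoding_diff = 1 flags alleles whose non-coding (5'UTR/intron/3'UTR)
# sequence differs from the reference allele of comparison.
allele	compared_to	accession	submission	coding_added	exons_added	noncoding_added	noncoding_diff
A*03:13	A*03:01:01:01	OW739111	HWS10061654	552	1,4,5,6,7,8	2402	0
A*03:182	A*03:01:01:01	OW739112	HWS10061658	86	6,7,8	2402	1
A*24:121	A*24:02:01:01	OW739113	HWS10061660	552	1,4,5,6,7,8	2379	0
A*33:03:07	A*33:01:01:01	OW739110;OX424589	HWS10061648;HWS10065531	552	1,4,5,6,7,8	2419	0
B*07:23	B*07:02:01:01	OW738604	HWS10061722	543	1,4,5,6,7	2670	0
B*07:24	B*07:02:01:01	OW738597;OX424582	HWS10061662;HWS10065533	543	1,4,5,6,7	2894	0
B*08:01:05	B*08:01:01:01	OW738598	HWS10061664	267	1,5,6,7	1763	0
B*15:107	B*15:01:01:01	OW738599	HWS10061666	543	1,4,5,6,7	2865	0
B*18:34	B*18:01:01:01	OW738606;OX421043	HWS10061724;HWS10065633	543	1,4,5,6,7	3750	1
B*27:23	B*27:01	OW738600;OX424587	HWS10061684;HWS10065535	543	1,4,5,6,7	2953	0
B*40:38	B*40:01:02:01	OW738601;OX424581	HWS10061680;HWS10065635	543	1,4,5,6,7	2894	0
B*44:13	B*44:02:01:01	OW738602	HWS10061686	0		2223	0
B*44:22	B*44:02:01:01	OW738603;OX424584	HWS10061690;HWS10065549	543	1,4,5,6,7	2894	0
B*44:90	B*44:02:01:01	OW738605	HWS10061720	543	1,4,5,6,7	2214	0
B*51:136	B*51:01:01:01	OW738607	HWS10061738	77	6,7	2897	0
B*53:06	B*53:01:01:01	OX421017	HWS10065637	543	1,4,5,6,7	2765	1
C*03:04:19	C*03:04:01:01	OW738943;OX424586	HWS10061742;HWS10065585	555	1,4,5,6,7,8	3102	1
C*06:11	C*06:02:01:01	OW738945	HWS10061748	555	1,4,5,6,7,8	3079	0
C*16:201	C*16:01:01:01	OW738944;OX424585	HWS10061744;HWS10065605	555	1,4,5,6,7,8	3017	1
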