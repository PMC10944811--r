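# table1B: 7 HLA class II alleles extended to full-length sequence; columns
# as in table1A. All seven alleles showed non-coding differences against the
# reference allele of comparison.
allele	compared_to	accession	submission	coding_added	exons_added	noncoding_added	noncoding_diff
DQA1*01:06	DQA1*01:01:01:01	OW849871	HWS10061752	519	1,3,4	4915	1
DQA1*04:04	DQA1*04:01:01:01	OW849870	HWS10061754	240	1,4	5024	1
DQB1*03:114	DQB1*03:01:01:01	OW849941	HWS10061756	234	1,4,5,6	6242	1
DQB1*06:03:11	DQB1*06:01:01:01	OW849942	HWS10061768	516	1,3,4,5,6	6035	1
DQB1*06:73	DQB1*06:01:01:01	OW849944	HWS10061770	516	1,3,4,5,6	6120	1
DQB1*06:286	DQB1*06:01:01:01	OW849943	HWS10061782	14	6	6125	1
DPA1*01:03:14	DPA1*01:03:01:01	OW849872	HWS10061750	100	1	4706	1
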