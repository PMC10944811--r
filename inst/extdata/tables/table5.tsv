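# table5: 47 HLA class I alleles extended with 5'UTR and/or 3'UTR sequence,
# with the non-coding nucleotides added to each UTR and the differences found
# in the extended sequence against the reference allele. ref_fallback = 1
# flags a reference that is not the first allele of the group with a known
# genomic sequence (its 3'UTR was incomplete). footnote: a = compared with
# another allele group (no group member known to position 3698); b = last
# 131 bp unknown for every other group member; c = reference group carries 10
# shared differences against the studied alleles.
# Transcription note: in a few source cells the boundary between the 5'UTR
# and 3'UTR added counts is typographically ambiguous (e.g. A*29:95
# "150/231", B*51:01:01:14 "13/1811", C*07:46 "204/658", C*12:167 "373/794");
# the split consistent with neighbouring rows was chosen. Both readings leave
# every such 5'UTR cell nonzero and the difference lists untouched.
allele	compared_to	ref_fallback	accession	submission	utr5_added	utr3_added	differences	footnote
A*02:01:01:48	A*02:01:01:01	0	OX421037	HWS10065285	0	185
A*29:95	A*29:01:01:01	0	OX421046	HWS10065287	150	231
B*07:02:01:32	B*07:02:01:01	0	OX421012	HWS10065289	248	1022
B*07:06:01:01	B*07:02:01:01	0	OX463247	HWS10065965	0	659	T3358C;C3698G
B*07:436	B*07:02:01:01	0	OX421031	HWS10065291	0	659	C3053T;C3129T;G3341A;T3358C;T3472C;T3576C;A3636G
B*08:09	B*08:01:01:01	0	OX421023	HWS10065293	0	660
B*14:81	B*14:02:01:01	1	OX421015	HWS10065295	248	986
B*15:03:01:01	B*15:01:01:01	0	OX421050	HWS10065297	284	1022	C2902T;C3174T;T3524C;G3542A;C3622T;C3681A
B*15:07:01:02	B*15:01:01:01	0	OX421032	HWS10065299	16	766
B*15:13:01	B*15:01:01:01	0	OX421014	HWS10065301	16	1011	T3485C;T3524C;C3622T;C3681A
B*15:37	B*15:01:01:01	0	OX421035	HWS10065303	57	777	T3524C;G3542A;C3622T;C3681A
B*18:01:01:18	B*18:01:01:01	0	OX421036	HWS10065305	0	659	C3358T
B*18:18:01:02	B*18:01:01:01	0	OX421052	HWS10065309	0	983	T3014C;C3358T;C3472T;C3576T;C3609T;C3668A
B*18:144	B*18:01:01:01	0	OX421022	HWS10065307	0	670	C3358T;C3472T;C3576T;C3609T;C3668A
B*27:06:01:01	B*27:04:01	1	OX421057	HWS10065311	0	659	T3509A;G3531A
B*35:05:01:01	B*35:01:01:02	1	OX421028	HWS10065313	0	129	C3604T;C3611T
B*35:30:01:01	B*35:01:01:02	1	OX421047	HWS10065315	0	984	A3188C;T3255G;A3259G;G3317A;T3362C;G3363A;T3377G;G3381T;T3389C;G3416C;T3439C;T3461C;C3604T;C3611T
B*40:23	B*40:01:02:01	1	OX421021	HWS10065537	0	659
B*40:27:01	B*40:02:01:01	0	OX421054	HWS10065539	0	661
B*41:02:01:05	B*42:01:01:01	1	OX421040	HWS10065541	0	1005		a
B*44:02:01:14	B*44:02:01:01	0	OX421033	HWS10065543	0	659
B*44:03:01:14	B*44:02:01:01	0	OX421055	HWS10065545	0	660	T3412G;T3472C;T3506A;G3523A
B*44:04	B*44:02:01:01	0	OX421048	HWS10065547	16	659	T3412G;T3472C;T3506A;G3523A
B*49:01:01:02	B*49:01:01:01	0	OX421056	HWS10065551	0	659
B*51:01:01:14	B*51:01:01:01	0	OX421020	HWS10065553	13	1811	T3525C;G3702C
B*51:01:01:25	B*51:01:01:01	0	OX421034	HWS10065555	27	679	G3702C
B*51:01:01:31	B*51:01:01:01	0	OX421045	HWS10065557	0	699	C3439T;C3461T;C3613T;G3702C
B*56:01:01:03	B*56:01:01:15	1	OX463248	HWS10065969	0	659
B*81:01:01:04	B*81:01:01:01	0	OX421058	HWS10065559	248	1022		b
C*02:02:02:06	C*02:02:02:01	0	OX421019	HWS10065561	0	235
C*02:02:02:14	C*02:02:02:01	0	OX421044	HWS10065569	19	2638
C*02:02:02:20	C*02:02:02:01	0	OX421016	HWS10065571	21	2638
C*02:02:02:27	C*02:02:02:01	0	OX421027	HWS10065573	43	1797
C*02:06:01	C*02:02:02:01	0	OX421038	HWS10065575	20	1652
C*03:02:02:02	C*03:02:02:01	1	OX421051	HWS10065577	21	2589	A3196G;G3200C;C3305T;G3325T;A3372C;3387_3388insG;C3423T;G3429A;C3439T;G3498A	c
C*03:03:01:22	C*03:02:02:01	1	OX421018	HWS10065581	43	1801	A3196G;G3200C;C3305T;G3325T;A3372C;3387_3388insG;C3423T;G3429A;C3439T;G3498A	c
C*03:04:02:01	C*03:02:02:01	1	OX421042	HWS10065583	0	278	A3196G;G3200C;C3305T;G3325T;A3372C;3387_3388insG;C3423T;G3429A;C3439T;G3498A	c
C*04:01:01:19	C*04:01:01:06	1	OX421049	HWS10065587	11	1620
C*04:01:01:38	C*04:01:01:06	1	OX421029	HWS10065589	43	1820
C*06:02:01:21	C*06:02:01:01	0	OX421024	HWS10065591	43	1819	G3033C
C*07:02:01:44	C*07:01:01:01	0	OX421030	HWS10065593	435	819	G3000A;T3001C
C*07:46	C*07:01:01:01	0	OX421053	HWS10065595	204	658
C*12:03:01:28	C*12:02:02:01	0	OX421039	HWS10065597	43	1794	C3638T;G3664A
C*12:143	C*12:02:02:01	0	OX421025	HWS10065599	0	291	C3638T;G3664A
C*12:167	C*12:02:02:01	0	OX421013	HWS10065601	373	794	G3664A
C*15:06:01:01	C*15:02:01:01	0	OX421026	HWS10065603	0	291
C*17:01:01:05	C*17:01:01:02	0	OX421041	HWS10065607	0	286
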