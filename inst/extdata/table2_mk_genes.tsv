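gene	protein_id	Dn	Ds	Pn	Ps	p_printed	FI_printed	divergence_methods
TLE6	ENSP00000403096	9	2	0	4	0.004	.	BS
USHBP1	ENSP00000252597	11	2	2	5	0.016	.	Accelerated
SYBU	ENSP00000415654	3	1	0	4	0.025	.	Accelerated
C20orf96	ENSP00000353470	11	2	1	3	0.04	.	BS
TXLNB	ENSP00000351206	7	1	2	4	0.043	14	Accelerated;BS
TLE4	ENSP00000365703	14	4	0	2	0.044	.	BS
FBF1	ENSP00000401215	13	1	5	4	0.044	10.4	Accelerated;BS
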