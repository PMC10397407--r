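step	outcome	gene	snp	scale	estimate	ci_lower	ci_upper	pvalue
1	LDL_C	PPARG	rs310749	beta	-0.183	-0.259	-0.107	1.97e-06
1	LDL_C	HMGCR	rs3846662	beta	-0.384	-0.425	-0.343	4.26e-74
1	LDL_C	PCSK9	rs11583974	beta	-0.248	-0.336	-0.160	3.36e-08
1	LDL_C	NPC1L1	rs41279633	beta	-0.109	-0.137	-0.081	8.41e-14
2	FA_BMD	PPARG	rs310749	beta	-2.362	-4.121	-0.604	0.008
2	FA_BMD	HMGCR	rs3846662	beta	-0.086	-0.539	0.366	0.708
2	FN_BMD	PPARG	rs310749	beta	-1.381	-2.218	-0.544	0.001
2	FN_BMD	HMGCR	rs3846662	beta	-0.045	-0.263	0.172	0.682
2	LS_BMD	PPARG	rs310749	beta	-2.068	-3.044	-1.091	3.35e-05
2	LS_BMD	HMGCR	rs3846662	beta	0.019	-0.234	0.272	0.878
2	fracture	PPARG	rs310749	or	3.469	1.392	8.645	0.008
2	fracture	HMGCR	rs3846662	or	1.149	0.912	1.449	0.241
2	fracture	PCSK9	rs11583974	or	0.734	0.359	1.501	0.396
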