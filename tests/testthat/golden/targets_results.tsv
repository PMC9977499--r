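subunit	direction	a	b	c	d	odds_ratio	or_cmle	p_value	fraction_pct	target_genes
p65	up	0	0	30	170	1.00000e+00	0.00000e+00	1.00000e+00	NA	
p65	down	0	0	30	170	1.00000e+00	0.00000e+00	1.00000e+00	NA	
p50	up	0	0	32	168	1.00000e+00	0.00000e+00	1.00000e+00	NA	
p50	down	0	0	32	168	1.00000e+00	0.00000e+00	1.00000e+00	NA	
RelB	up	0	0	18	182	1.00000e+00	0.00000e+00	1.00000e+00	NA	
RelB	down	0	0	18	182	1.00000e+00	0.00000e+00	1.00000e+00	NA	
p52	up	0	0	25	175	1.00000e+00	0.00000e+00	1.00000e+00	NA	
p52	down	0	0	25	175	1.00000e+00	0.00000e+00	1.00000e+00	NA	
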