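partition	pct_t	pct_c	pct_a	pct_g	pct_at	at_skew	gc_skew
Whole genome	44.6	6.8	46.2	2.4	90.7	0.017	-0.475
Protein-coding genes	47.8	6.1	41.2	5.0	88.9	-0.074	-0.096
PCG first codon position	37.9	5.6	50.2	6.3	88.1	0.141	0.057
PCG second codon position	56.5	7.4	29.9	6.2	86.4	-0.308	-0.083
PCG third codon position	48.9	5.2	43.4	2.5	92.3	-0.060	-0.353
Protein-coding genes J-strand	45.3	8.3	42.3	4.1	87.6	-0.035	-0.346
PCG J-strand first codon position	33.0	7.7	54.3	5.0	87.3	0.244	-0.211
PCG J-strand second codon position	54.8	10.0	28.9	6.3	83.7	-0.309	-0.229
PCG J-strand third codon position	48.2	7.3	43.6	0.9	91.8	-0.051	-0.781
Protein-coding genes N-strand	51.6	2.4	39.4	6.5	91.1	-0.134	0.464
PCG N-strand first codon position	45.6	2.3	43.7	8.4	89.4	-0.021	0.572
PCG N-strand second codon position	59.2	3.1	31.5	6.2	90.8	-0.306	0.333
PCG N-strand third codon position	50.1	1.8	43.0	5.1	93.0	-0.075	0.474
tRNA genes	44.6	3.1	47.9	4.4	92.5	0.036	0.172
tRNA genes J-strand	44.1	4.1	48.3	3.6	92.4	0.045	-0.065
tRNA genes N-strand	45.5	1.4	47.3	5.8	92.8	0.020	0.600
rRNA genes	46.3	2.4	44.6	6.8	90.8	-0.018	0.479
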