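gene	strand	start	end	anticodon	start_codon	stop_codon	printed_length	printed_intergenic
COI	J	1	1551	-	ATT	TAA	1551	0
trnL2	J	1560	1623	TAA 1592-1594	-	-	64	8
trnD	J	1626	1685	GTC 1663-1665	-	-	60	2
ATP8	J	1686	1826	-	ATT	TAA	141	0
ATP6	J	1820	2431	-	ATG	TAA	612	-7
COIII	J	2463	3215	-	ATG	TAA	753	31
trnA	J	3200	3275	TGC 3237-3239	-	-	76	-15
trnR	J	3268	3312	TCG 3294-3296	-	-	45	-4
trnN	J	3322	3378	GTT 3343-3345	-	-	57	9
trnE	J	3376	3431	TTC 3406-3408	-	-	56	-3
trnF	N	3432	3496	GAA 3449-3451	-	-	66	0
trnH	N	3518	3587	GTG 3552-3554	-	-	69	21
ND6	J	3586	4065	-	ATT	TAA	480	-2
trnS1	J	4068	4124	TGA 4085-4087	-	-	57	2
trnQ	N	4152	4205	TTG 4186-4188	-	-	54	27
ND1	N	4218	5120	-	ATT	TAA	903	12
trnL1	N	5120	5194	TAG 5155-5157	-	-	75	-1
lrRNA	N	5195	6388	-	-	-	1194	0
trnV	N	6389	6452	TAC 6416-6418	-	-	64	0
trnI	J	6504	6573	GAT 6539-6541	-	-	70	51
trnM	J	6574	6639	CAT 6607-6609	-	-	65	0
ND2	J	6640	7581	-	ATT	TAA	942	0
trnW	J	7580	7635	TCA 7612-7614	-	-	56	-2
trnY	N	7634	7704	GTA 7668-7670	-	-	71	-2
COII	J	7777	8448	-	ATA	TAA	672	72
trnK	J	8450	8519	TTT 8510-8512	-	-	70	1
trnG	J	8557	8612	TCC 8587-8589	-	-	56	37
ND3	J	8610	8963	-	ATA	TAA	354	-3
trnS2	J	8959	9012	TCT 8986-8988	-	-	58	-5
ND5	N	9034	10662	-	ATT	TAA	1629	17
ND4	N	10650	11918	-	ATT	TAA	1269	-13
ND4L	N	11914	12207	-	ATT	TAA	294	-5
trnT	J	12190	12248	TGT 12222-12224	-	-	59	-18
trnP	N	12247	12303	AGG 12269-12271	-	-	57	-2
trnC	N	12282	12321	GCA 12302-12304	-	-	40	-22
cytb	J	12336	13418	-	ATG	TAA	1083	14
srRNA	N	15769	16377	-	-	-	609	2350
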