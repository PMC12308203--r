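alias	canonical
cox1	COI
cox2	COII
cox3	COIII
co1	COI
co2	COII
co3	COIII
coxi	COI
coxii	COII
coxiii	COIII
cytochrome c oxidase subunit 1	COI
cytochrome c oxidase subunit 2	COII
cytochrome c oxidase subunit 3	COIII
nad1	ND1
nad2	ND2
nad3	ND3
nad4	ND4
nad4l	ND4L
nad5	ND5
nad6	ND6
nadh1	ND1
nadh2	ND2
nadh3	ND3
nadh4	ND4
nadh5	ND5
nadh6	ND6
cob	cytb
cytB	cytb
cyt b	cytb
cytochrome b	cytb
atp8	ATP8
atp6	ATP6
atpase6	ATP6
atpase8	ATP8
12s	srRNA
12s rrna	srRNA
rrns	srRNA
s-rrna	srRNA
small subunit ribosomal rna	srRNA
16s	lrRNA
16s rrna	lrRNA
rrnl	lrRNA
l-rrna	lrRNA
large subunit ribosomal rna	lrRNA
trna-ala	trnA
trna-arg	trnR
trna-asn	trnN
trna-asp	trnD
trna-cys	trnC
trna-gln	trnQ
trna-glu	trnE
trna-gly	trnG
trna-his	trnH
trna-ile	trnI
trna-lys	trnK
trna-met	trnM
trna-phe	trnF
trna-pro	trnP
trna-thr	trnT
trna-trp	trnW
trna-tyr	trnY
trna-val	trnV
trna-ser1	trnS1
trna-ser2	trnS2
trna-leu1	trnL1
trna-leu2	trnL2
trnl1	trnL1
trnl2	trnL2
trns1	trnS1
trns2	trnS2
d-loop	CR
control region	CR
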