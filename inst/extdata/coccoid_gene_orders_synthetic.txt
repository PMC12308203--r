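# Schematic circular signed gene orders (synthetic stand-in; see package
# documentation). One taxon per line: taxon label, whitespace, then
# comma-separated signed gene labels; "-" marks the minority (N) strand.
# Only the documented ND2-neighborhood clusters and named gene blocks are
# encoded per taxon; all other genes remain in the ancestral arrangement.
ancestor	trnI,-trnQ,trnM,ND2,trnW,-trnC,-trnY,COI,trnL2,COII,trnK,trnD,ATP8,ATP6,COIII,trnG,ND3,trnA,trnR,trnN,trnS1,trnE,-trnF,-ND5,-trnH,-ND4,-ND4L,trnT,-trnP,ND6,cytb,trnS2,-ND1,-trnL1,-lrRNA,-trnV,-srRNA
Matsucoccus_matsumurae	trnI,-trnQ,trnM,ND2,trnW,-trnY,-trnC,COI,trnL2,COII,trnK,trnD,ATP8,ATP6,COIII,trnG,ND3,trnA,trnR,trnN,trnS1,trnE,-trnF,-ND5,-trnH,-ND4,-ND4L,trnT,-trnP,ND6,cytb,trnS2,-ND1,-trnL1,-lrRNA,-trnV,-srRNA
Icerya_purchasi	trnI,-trnQ,trnM,ND2,trnW,-trnC,-trnY,COI,trnL2,COII,trnK,trnD,ATP8,ATP6,COIII,trnG,ND3,trnA,trnR,trnN,trnS1,trnE,-trnF,-ND5,-trnH,-ND1,-trnL1,-ND4,-trnP,-srRNA,trnT,cytb,trnS2,-ND4L,ND6,-lrRNA,-trnV
Coronaproctus_castanopsis	trnI,-trnQ,trnM,ND2,trnW,-trnC,-trnY,COI,trnL2,COII,trnK,trnD,ATP8,ATP6,COIII,trnG,ND3,trnA,trnR,trnN,trnS1,trnE,-trnF,-ND5,-trnH,-ND1,-trnL1,-ND4,-trnP,-srRNA,trnT,cytb,trnS2,-ND4L,ND6,-lrRNA,-trnV
Puto_sinensis	COI,trnL2,trnD,ATP8,ATP6,COIII,trnA,trnR,trnN,trnE,-trnF,-trnH,ND6,trnS1,-trnQ,-ND1,-trnL1,-lrRNA,-trnV,trnI,trnM,ND2,trnW,-trnY,COII,trnK,trnG,ND3,trnS2,-ND5,-ND4,-ND4L,trnT,-trnP,-trnC,cytb,-srRNA
Paracoccus_marginatus	trnI,ND2,trnW,COI,trnL2,COII,trnK,trnD,ATP8,ATP6,COIII,trnG,ND3,trnA,trnR,trnN,trnS1,trnE,-trnF,-ND5,-trnH,-ND4,-ND4L,trnT,-trnP,ND6,cytb,trnS2,trnM,-trnQ,-trnY,-trnC,-ND1,-trnL1,-lrRNA,-trnV,-srRNA
Phenacoccus_aceris	-trnY,ND2,trnW,COI,trnL2,COII,trnK,trnD,ATP8,ATP6,COIII,trnG,ND3,trnA,trnR,trnN,trnS1,trnE,-trnF,-ND5,-trnH,-ND4,-ND4L,trnT,-trnP,ND6,cytb,trnS2,trnI,trnM,-trnQ,-trnC,-ND1,-trnL1,-lrRNA,-trnV,-srRNA
Phenacoccus_manihoti	trnI,ND2,-trnY,COI,trnL2,COII,trnK,trnD,ATP8,ATP6,COIII,trnG,ND3,trnA,trnR,trnN,trnS1,trnE,-trnF,-ND5,-trnH,-ND4,-ND4L,trnT,-trnP,ND6,cytb,trnS2,trnM,-trnQ,trnW,-trnC,-ND1,-trnL1,-lrRNA,-trnV,-srRNA
Acanthococcus_coriaceus	trnI,ND2,trnW,COI,trnL2,COII,trnK,trnD,ATP8,ATP6,COIII,trnG,ND3,trnA,trnR,trnN,trnS1,trnE,-trnF,-ND5,-trnH,-ND4,-ND4L,trnT,-trnP,ND6,cytb,trnS2,trnM,-trnQ,-trnY,-trnC,-ND1,-trnL1,-lrRNA,-trnV,-srRNA
Apiomorpha_munita	-trnQ,ND2,trnW,COI,trnL2,COII,trnK,trnD,ATP8,ATP6,COIII,trnG,ND3,trnA,trnR,trnN,trnS1,trnE,-trnF,-ND5,-trnH,-ND4,-ND4L,trnT,-trnP,ND6,cytb,trnS2,trnI,trnM,-trnY,-trnC,-ND1,-trnL1,-lrRNA,-trnV,-srRNA
Albotachardina_sinensis	trnI,ND2,-trnY,COI,trnL2,COII,trnK,trnD,ATP8,ATP6,COIII,trnG,ND3,trnA,trnR,trnN,trnS1,trnE,-trnF,-ND5,-trnH,-ND4,-ND4L,trnT,-trnP,ND6,cytb,trnS2,trnM,-trnQ,trnW,-trnC,-ND1,-trnL1,-lrRNA,-trnV,-srRNA
Antecerococcus_theydoni	trnI,ND2,-trnY,COI,trnL2,COII,trnK,trnD,ATP8,ATP6,COIII,trnG,ND3,trnA,trnR,trnN,trnS1,trnE,-trnF,-ND5,-trnH,-ND4,-ND4L,trnT,-trnP,ND6,cytb,trnS2,trnM,-trnQ,trnW,-trnC,-ND1,-trnL1,-lrRNA,-trnV,-srRNA
Nipponaclerda_biwakoensis	trnI,ND2,-trnY,COI,trnL2,COII,trnK,trnD,ATP8,ATP6,COIII,trnG,ND3,trnA,trnR,trnN,trnS1,trnE,-trnF,-ND5,-trnH,-ND4,-ND4L,trnT,-trnP,ND6,cytb,trnS2,trnM,-trnQ,trnW,-trnC,-ND1,-trnL1,-lrRNA,-trnV,-srRNA
Aclerda_takahashii	trnI,ND2,-trnY,COI,trnL2,COII,trnK,trnD,ATP8,ATP6,COIII,trnG,ND3,trnA,trnR,trnN,trnS1,trnE,-trnF,-ND5,-trnH,-ND4,-ND4L,trnT,-trnP,ND6,cytb,trnS2,trnM,-trnQ,trnW,-trnC,-ND1,-trnL1,-lrRNA,-trnV,-srRNA
Didesmococcus_koreanus	trnI,ND2,-trnY,COI,trnL2,COII,trnK,trnD,ATP8,ATP6,COIII,trnG,ND3,trnA,trnR,trnN,trnS1,trnE,-trnF,-ND5,-trnH,-ND4,-ND4L,trnT,-trnP,ND6,cytb,trnS2,trnM,-trnQ,trnW,-trnC,-ND1,-trnL1,-lrRNA,-trnV,-srRNA
Saissetia_coffeae	trnI,ND2,-trnY,COI,trnL2,COII,trnK,trnD,ATP8,ATP6,COIII,trnG,ND3,trnA,trnR,trnN,trnS1,trnE,-trnF,-ND5,-trnH,-ND4,-ND4L,trnT,-trnP,ND6,cytb,trnS2,trnM,-trnQ,trnW,-trnC,-ND1,-trnL1,-lrRNA,-trnV,-srRNA
Parasaissetia_nigra	trnI,ND2,-trnY,COI,trnL2,COII,trnK,trnD,ATP8,ATP6,COIII,trnG,ND3,trnA,trnR,trnN,trnS1,trnE,-trnF,-ND5,-trnH,-ND4,-ND4L,trnT,-trnP,ND6,cytb,trnS2,trnM,-trnQ,trnW,-trnC,-ND1,-trnL1,-lrRNA,-trnV,-srRNA
Ceroplastes_japonicus	trnI,ND2,-trnY,COI,trnL2,COII,trnK,trnD,ATP8,ATP6,COIII,trnG,ND3,trnA,trnR,trnN,trnS1,trnE,-trnF,-ND5,-trnH,-ND4,-ND4L,trnT,-trnP,ND6,cytb,trnS2,trnM,-trnQ,trnW,-trnC,-ND1,-trnL1,-lrRNA,-trnV,-srRNA
Ceroplastes_floridensis	trnI,ND2,-trnY,COI,trnL2,COII,trnK,trnD,ATP8,ATP6,COIII,trnG,ND3,trnA,trnR,trnN,trnS1,trnE,-trnF,-ND5,-trnH,-ND4,-ND4L,trnT,-trnP,ND6,cytb,trnS2,trnM,-trnQ,trnW,-trnC,-ND1,-trnL1,-lrRNA,-trnV,-srRNA
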