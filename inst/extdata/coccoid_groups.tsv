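taxon	group
Matsucoccus_matsumurae	non_neococcoid
Icerya_purchasi	non_neococcoid
Coronaproctus_castanopsis	non_neococcoid
Puto_sinensis	non_neococcoid
Paracoccus_marginatus	neococcoid
Phenacoccus_aceris	neococcoid
Phenacoccus_manihoti	neococcoid
Acanthococcus_coriaceus	neococcoid
Apiomorpha_munita	neococcoid
Albotachardina_sinensis	neococcoid
Antecerococcus_theydoni	neococcoid
Nipponaclerda_biwakoensis	neococcoid
Aclerda_takahashii	neococcoid
Didesmococcus_koreanus	neococcoid
Saissetia_coffeae	neococcoid
Parasaissetia_nigra	neococcoid
Ceroplastes_japonicus	neococcoid
Ceroplastes_floridensis	neococcoid
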