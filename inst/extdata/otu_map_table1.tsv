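# Operational taxonomic units (OTUs) of the combined analysis: each OTU
# joins one morphologically scored species with GenBank sequences of the
# same or a closely related species, per gene partition.  34 OTUs are
# scored for morphology; 33 of them carry at least one sequence (Xaiva
# biguttata has no molecular data and enters on morphology alone).
# Gene assignment of accessions is a best-effort transcription of the
# source table (reading order 16S, COI, NADH1, H3; a single mitogenome
# accession may serve several mitochondrial partitions).
otu	gene	source_taxon	accession
Ashtoret_lunaris	16S	Ashtoret_lunaris	LK391941
Ashtoret_lunaris	COI	Ashtoret_lunaris	LK391941
Ashtoret_lunaris	NADH1	Ashtoret_lunaris	LK391941
Ashtoret_lunaris	H3	Matuta_planipes	KJ133142
Bathynectes_maravigna	16S	Bathynectes_maravigna	FM208770
Bathynectes_maravigna	COI	Bathynectes_maravigna	FM208770
Bathynectes_maravigna	NADH1	Bathynectes_maravigna	FM208814
Bathynectes_maravigna	H3	Bathynectes_maravigna	JQ305964
Calappa_granulata	16S	Calappa_granulata	KU206591
Calappa_granulata	COI	Calappa_granulata	KU206702
Calappa_granulata	NADH1	Calappa_granulata	JQ306054
Calappa_granulata	H3	Calappa_bilineata	MN562587
Callinectes_sapidus	16S	Callinectes_sapidus	AY363392
Callinectes_sapidus	COI	Callinectes_sapidus	AY363392
Callinectes_sapidus	NADH1	Callinectes_sapidus	AY363392
Callinectes_sapidus	H3	Callinectes_sapidus	FM208798
Cancer_pagurus	16S	Cancer_pagurus	FM207653
Cancer_pagurus	COI	Cancer_pagurus	FM207653
Cancer_pagurus	NADH1	Cancer_pagurus	FM208806
Cancer_pagurus	H3	Cancer_pagurus	JQ306000
Cancer_irroratus	16S	Cancer_irroratus	FM207654
Cancer_irroratus	COI	Cancer_irroratus	FM208807
Cancer_irroratus	NADH1	Cancer_irroratus	FJ581562
Caphyra_loevis	16S	Caphyra_loevis	KT365592
Caphyra_loevis	COI	Caphyra_loevis	KT365697
Caphyra_loevis	NADH1	Caphyra_loevis	KT425009
Caphyra_rotundifrons	16S	Caphyra_rotundifrons	KT365530
Caphyra_rotundifrons	COI	Caphyra_rotundifrons	KT365698
Caphyra_rotundifrons	NADH1	Caphyra_rotundifrons	KT365530
Caphyra_rotundifrons	H3	Caphyra_rotundifrons	KT424989
Carcinus_maenas	16S	Carcinus_maenas	FM208763
Carcinus_maenas	COI	Carcinus_maenas	FM208763
Carcinus_maenas	NADH1	Carcinus_maenas	FM208811
Carcinus_maenas	H3	Carcinus_maenas	FJ581597
Carupa_tenuipes	16S	Carupa_tenuipes	FM208758
Carupa_tenuipes	COI	Carupa_tenuipes	FM208758
Carupa_tenuipes	NADH1	Carupa_tenuipes	FM208789
Carupa_tenuipes	H3	Carupa_tenuipes	KT365703
Catoptrus_nitidus	16S	Catoptrus_nitidus	FM208755
Catoptrus_nitidus	COI	Catoptrus_nitidus	FM208755
Catoptrus_nitidus	NADH1	Catoptrus_aff_nitidus	KT365706
Chaceon_mediterraneus	16S	Chaceon_granulatus	FM208775
Chaceon_mediterraneus	COI	Chaceon_granulatus	FM208775
Chaceon_mediterraneus	NADH1	Chaceon_granulatus	FM208827
Chaceon_mediterraneus	H3	Chaceon_granulatus	AB769383
Coelocarcinus_foliatus	16S	Coelocarcinus_foliatus	KT365601
Coelocarcinus_foliatus	COI	Coelocarcinus_foliatus	KT365724
Coelocarcinus_foliatus	NADH1	Coelocarcinus_foliatus	KT425058
Coelocarcinus_foliatus	H3	Coelocarcinus_sp	KT365545
Corystes_cassivelaunus	16S	Corystes_cassivelaunus	FM208781
Corystes_cassivelaunus	COI	Corystes_cassivelaunus	FM208781
Corystes_cassivelaunus	NADH1	Corystes_cassivelaunus	FM208801
Corystes_cassivelaunus	H3	Corystes_cassivelaunus	JQ306005
Eriocheir_sinensis	16S	Eriocheir_sinensis	KP064329
Eriocheir_sinensis	COI	Eriocheir_sinensis	KP064329
Eriocheir_sinensis	NADH1	Eriocheir_sinensis	KP064329
Eriocheir_sinensis	H3	Eriocheir_japonica	KJ133099
Libystes_nitidus	16S	Libystes_nitidus	FM208762
Libystes_nitidus	COI	Libystes_nitidus	FM208762
Libystes_nitidus	NADH1	Libystes_nitidus	KT365728
Liocarcinus_depurator	16S	Liocarcinus_depurator	FM208767
Liocarcinus_depurator	COI	Liocarcinus_depurator	FM208767
Liocarcinus_depurator	NADH1	Liocarcinus_depurator	FM208819
Liocarcinus_depurator	H3	Liocarcinus_depurator	JQ306013
Liocarcinus_navigator	16S	Liocarcinus_navigator	FM208821
Liocarcinus_navigator	COI	Liocarcinus_navigator	KU560476
Liocarcinus_navigator	NADH1	Liocarcinus_navigator	KP795939
Liocarcinus_navigator	H3	Liocarcinus_navigator	KU560476
Lissocarcinus_orbicularis	16S	Lissocarcinus_orbicularis	FM208757
Lissocarcinus_orbicularis	COI	Lissocarcinus_orbicularis	FM208757
Lissocarcinus_orbicularis	NADH1	Lissocarcinus_orbicularis	FM208791
Lissocarcinus_orbicularis	H3	Lissocarcinus_orbicularis	KT365732
Macropipus_rugosus	16S	Macropipus_tuberculatus	FM208769
Macropipus_rugosus	COI	Macropipus_tuberculatus	FM208769
Macropipus_rugosus	NADH1	Macropipus_tuberculatus	FM208815
Macropipus_rugosus	H3	Macropipus_tuberculatus	JQ306218
Medorippe_lanata	16S	Medorippe_lanata	EU636950
Medorippe_lanata	COI	Medorippe_lanata	EU636981
Medorippe_lanata	NADH1	Dorippe_quadridens	KJ133093
Necora_puber	16S	Necora_puber	FM208771
Necora_puber	COI	Necora_puber	FM208771
Necora_puber	NADH1	Necora_puber	FM208813
Necora_puber	H3	Necora_puber	FJ755619
Ovalipes_ocellatus	16S	Ovalipes_punctatus	FM208824
Ovalipes_ocellatus	COI	Ovalipes_punctatus	MH802052
Ovalipes_ocellatus	NADH1	Ovalipes_punctatus	MH802052
Ovalipes_ocellatus	H3	Ovalipes_punctatus	MH802052
Parathranites_orientalis	16S	Parathranites_orientalis	KJ132616
Parathranites_orientalis	COI	Parathranites_orientalis	KJ133173
Pirimela_denticulata	16S	Pirimela_denticulata	FM208783
Pirimela_denticulata	COI	Pirimela_denticulata	FM208783
Pirimela_denticulata	NADH1	Pirimela_denticulata	FM208808
Polybius_henslowii	16S	Polybius_henslowii	FM208765
Polybius_henslowii	COI	Polybius_henslowii	FM208765
Polybius_henslowii	NADH1	Polybius_henslowii	FM208816
Polybius_henslowii	H3	Polybius_henslowii	JQ306293
Portumnus_latipes	16S	Portumnus_latipes	FM208764
Portumnus_latipes	COI	Portumnus_latipes	FM208764
Portumnus_latipes	NADH1	Portumnus_latipes	FM208812
Portunus_inaequalis	16S	Portunus_inaequalis	FM208752
Portunus_inaequalis	COI	Portunus_inaequalis	FM208752
Portunus_inaequalis	NADH1	Portunus_inaequalis	FM208795
Portunus_inaequalis	H3	Portunus_pelagicus	KR153996
Raymanninus_schmitti	16S	Raymanninus_schmitti	KT365560
Raymanninus_schmitti	COI	Raymanninus_schmitti	KT365560
Sternodromia_monodi	16S	Lauridromia_dehaani	AY583899
Sternodromia_monodi	COI	Lauridromia_dehaani	EU636986
Sternodromia_monodi	NADH1	Lauridromia_dehaani	KJ133125
Sternodromia_monodi	H3	Lauridromia_dehaani	MT038417
Telmessus_cheiragonus	16S	Telmessus_cheiragonus	FM207656
Telmessus_cheiragonus	COI	Telmessus_cheiragonus	FM207656
Telmessus_cheiragonus	NADH1	Telmessus_cheiragonus	FM208802
Telmessus_cheiragonus	H3	Telmessus_cheiragonus	KX039796
Thia_scutellata	16S	Thia_scutellata	FM208782
Thia_scutellata	COI	Thia_scutellata	FM208782
Thia_scutellata	NADH1	Thia_scutellata	FM208810
Thia_scutellata	H3	Thia_scutellata	KT209396
Varuna_litterata	16S	Varuna_litterata	MW125542
Varuna_litterata	COI	Varuna_litterata	MW125542
Varuna_litterata	NADH1	Varuna_litterata	MW125542
Varuna_litterata	H3	Varuna_litterata	FN434060
Xaiva_biguttata	NA	NA	NA
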