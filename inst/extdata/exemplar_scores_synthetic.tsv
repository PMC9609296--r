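# SYNTHETIC stand-in rows for a few exemplar species, restricted to the
# morphotype-rule characters, their controllers (7, 8, 42) and merus length
# (44).  These are NOT the published full scores (the complete matrix is a
# supplementary data file of the source study); each cell is reconstructed
# from explicit statements in the study's text where available and filled
# with morphotype-consistent values otherwise.  Used only to exercise the
# classifier on named exemplars.
taxon	7	8	11	15	16	18	23	34	42	43	44	45	46	47	48	50
Liocarcinus_depurator	1	1	1	1	1	2	0	2	0	0	1	1	1	1	1	0
Polybius_henslowii	1	1	1	1	1	2	0	2	0	0	1	1	1	1	1	0
Carcinus_maenas	1	1	1	1	1	2	0	1	0	1	0	0	0	0	0	0
Chaceon_mediterraneus	1	1	1	1	1	2	0	0	0	1	0	0	0	0	0	0
Xaiva_biguttata	1	1	1	1	1	2	0	3	0	0	0	1	0	1	1	0
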