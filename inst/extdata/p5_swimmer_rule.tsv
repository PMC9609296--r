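# P5-swimming-crab morphotype rule: character states shared by all
# P5-swimmers in the study sample (one row per rule character; allowed
# states separated by '/'). Merus length (character 44) is deliberately
# not part of the rule: it only grades swimming effectiveness.
char_id	allowed_states	statement
11	1	Sternum, median plate, dorsal margin, shape: more or less convex, without indentations and/or gaps between thoracomeres
15	1	Sternum, interosternite 6/7, connection to median plate: absent
16	1	Sternum, interosternite 7/8, connection to median plate: absent
18	2	Sternum, interosternite 4/5, medial margin, shape: transversal with lower margin being most medial, but not touching interosternite 4/5 of other lateral side
23	0	Sella turcica, covering of dorsal median plate margin: present
34	2/3	Pereiopod 5, anterior coxa muscle, origin: at median plate + interosternite 7/8 OR at median plate + interosternite 7/8 + interopleurite 7/8
43	0	Pereiopod 5, long setae, arrangement: arranged in dense fringes along podomere margins
45	1	Pereiopod 5, carpus, disto-dorsal margin, propodus insertion: present
46	1	Pereiopod 5, propodus, lobe-like expansion of posterio-ventral margin: present
47	1	Pereiopod 5, dactylus, maximum width in relation to maximum width of P5 merus: larger
48	1	Pereiopod 5, dactylus, proximo-ventral margin, shape: concave
50	0	Carapace, maximum width in relation to maximum length: larger or equal
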