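cazyme_family	substrate
GH94	cellulose|cellobiose
GH9	cellulose
GH74	cellulose|xyloglucan
GH48	cellulose
GH8	cellulose|xylan
GH5	cellulose|xylan|mannan
GH39	xylan|cellulose
GH98	xylan
GH43	xylan|arabinan
GH30	xylan
GH11	xylan
GH10	xylan
GH26	xylan|mannan
GH141	xylan|pectin
GH115	xylan
GH67	xylan
GH4	glucuronoside|starch
GH51	arabinan|xylan
GH95	fucoside|galactoside
GH3	xylooligosaccharide|cellobiose
GH2	xylooligosaccharide|galactan
GH120	xylooligosaccharide
GT2	glycan_synthesis
GT4	glycan_synthesis
GT35	starch
CE1	xylan_deacetylation
SLH	cell_wall_anchoring
CBM6	xylan_binding|cellulose_binding
CBM22	xylan_binding
CBM4	xylan_binding|glucan_binding
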