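pathway	ko
Glycolysis / Gluconeogenesis	K00844
Glycolysis / Gluconeogenesis	K01810
Glycolysis / Gluconeogenesis	K00850
Glycolysis / Gluconeogenesis	K01623
Glycolysis / Gluconeogenesis	K00134
Glycolysis / Gluconeogenesis	K00927
Glycolysis / Gluconeogenesis	K01689
Glycolysis / Gluconeogenesis	K00873
Pentose phosphate pathway	K01810
Pentose phosphate pathway	K00850
Pentose phosphate pathway	K01623
Pentose phosphate pathway	K00853
Pentose phosphate pathway	K03077
Pentose and glucuronate interconversions	K01805
Pentose and glucuronate interconversions	K00854
Pentose and glucuronate interconversions	K01811
Pentose and glucuronate interconversions	K01804
Pentose and glucuronate interconversions	K00853
Pentose and glucuronate interconversions	K03077
Pentose and glucuronate interconversions	K01235
Pentose and glucuronate interconversions	K01209
Pentose and glucuronate interconversions	K15921
Starch and sucrose metabolism	K01179
Starch and sucrose metabolism	K00702
Starch and sucrose metabolism	K05349
Starch and sucrose metabolism	K05350
Starch and sucrose metabolism	K00688
Amino sugar and nucleotide sugar metabolism	K00963
Amino sugar and nucleotide sugar metabolism	K00975
Amino sugar and nucleotide sugar metabolism	K00844
Xylan degradation	K01181
Xylan degradation	K15924
Xylan degradation	K01198
Alanine, aspartate and glutamate metabolism	K01915
Alanine, aspartate and glutamate metabolism	K00265
Alanine, aspartate and glutamate metabolism	K01955
Alanine, aspartate and glutamate metabolism	K00812
Arginine biosynthesis	K01955
Arginine biosynthesis	K00812
Lysine biosynthesis	K01586
Lysine biosynthesis	K01714
Lysine biosynthesis	K00133
Lysine biosynthesis	K00928
Lysine degradation	K00290
Glycine, serine and threonine metabolism	K00003
Glycine, serine and threonine metabolism	K00133
Glycine, serine and threonine metabolism	K00928
Glycine, serine and threonine metabolism	K00600
Cysteine and methionine metabolism	K01738
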