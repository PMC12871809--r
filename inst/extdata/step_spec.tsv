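step_id	ko_ids
endoglucanase	K01179
beta_glucosidase	K05349|K05350
cellobiose_phosphorylase	K00702
endo_xylanase	K01181|K15924|K01198
xylosidase	K01811
xylose_isomerase	K01805
xylulokinase	K00854
arabinose_removal	K01209|K15921
arabinose_conversion	K01804|K00853|K03077
glucuronidase	K01235
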