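analyte	weight
XXL_VLDL_L	0.28
S_HDL_L	-0.25
VLDL_D	0.18
PUFA_FA_pct	-0.22
Glucose	0.19
Lactate	0.15
Histidine	-0.18
Isoleucine	0.16
Leucine	-0.15
Valine	-0.19
Phenylalanine	0.22
Acetoacetate	0.16
Albumin	-0.25
GlycA	0.31
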