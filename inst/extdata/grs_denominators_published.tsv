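parent_sex	adjustment	estimate	ci_lower	ci_upper	n
mother	unadjusted	0.055	0.052	0.058	233361
mother	adjusted	0.054	0.051	0.057	233361
father	unadjusted	0.045	0.042	0.047	233361
father	adjusted	0.044	0.041	0.046	233361
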