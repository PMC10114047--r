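parent_sex	offspring_sex	adjustment	estimate	ci_lower	ci_upper	n
mother	daughter	unadjusted	0.168	0.144	0.192	4696
mother	daughter	adjusted	0.139	0.118	0.161	4696
mother	son	unadjusted	0.192	0.164	0.220	4651
mother	son	adjusted	0.168	0.140	0.196	4651
father	daughter	unadjusted	0.079	0.061	0.097	4696
father	daughter	adjusted	0.064	0.048	0.080	4696
father	son	unadjusted	0.136	0.114	0.158	4651
father	son	adjusted	0.132	0.113	0.152	4651
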