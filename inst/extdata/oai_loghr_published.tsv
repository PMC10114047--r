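parent_sex	offspring_sex	adjustment	hr	se_loghr	n
mother	daughter	unadjusted	1.11	0.009	120489
mother	son	unadjusted	1.08	0.008	111148
mother	daughter	adjusted	1.11	0.010	120489
mother	son	adjusted	1.08	0.009	111148
father	daughter	unadjusted	1.22	0.025	118181
father	son	unadjusted	1.14	0.012	109699
father	daughter	adjusted	1.23	0.028	118181
father	son	adjusted	1.12	0.011	109699
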