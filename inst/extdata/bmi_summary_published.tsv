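sex	mean_bmi	sd_bmi	n
female	26.69	5.03	121044
male	27.59	4.10	112317
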