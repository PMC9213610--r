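species	tissue	n	n_female	mean_age_years	min_age_years	max_age_years
opossum	ear	45	28	0.771	0.0384	2.22
opossum	liver	48	26	0.922	0.0384	3.27
opossum	tail	7	4	0.164	0.0384	0.288
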