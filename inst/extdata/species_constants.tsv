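species	max_lifespan_years	maturity_years
opossum	4.2	0.5
human	122.5	13.5
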