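chemical	n_interacting	is_air_pollutant
resveratrol	3	FALSE
asbestos_crocidolite	2	TRUE
cadmium	2	TRUE
carbon_tetrachloride	2	TRUE
sodium_arsenite	2	TRUE
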