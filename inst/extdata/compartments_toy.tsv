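gene	category	score
GENEA	Extracellular region	3.0
GENEA	Extracellular exosome	4.5
GENEB	Extracellular space	5.0
GENEB	Extracellular vesicle	2.0
GENEC	Cytoplasm	5.0
GENED	Extracellular region	1.0
GENED	Nucleus	4.0
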