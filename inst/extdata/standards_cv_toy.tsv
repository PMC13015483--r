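platform	standard	cv
hilicpos	std1	0.06
hilicpos	std2	0.1
rppos	std1	0.12
rppos	std2	0.18
ionpneg	std1	0.06
ionpneg	std2	0.1
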