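feature_id	refmet_id	platform
f1	REFMET:X	hilicpos
f2	REFMET:X	rppos
f3	REFMET:Y	rppos
f4	REFMET:Z	hilicpos
f5	REFMET:Z	ionpneg
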