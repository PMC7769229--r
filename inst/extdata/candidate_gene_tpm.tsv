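gene_id	FP1	FP2	FP3	RP1	RP2	RP3
ovate_family_protein	51.36	60.15	95.02	2.20	0.84	5.93
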