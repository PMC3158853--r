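name	target	delta
Carbamidomethyl	C	C2 H3 N1 O1
Oxidation	M	O1
Phospho	STY	H1 P1 O3
Pyro-glu	nterm:Q	H-3 N-1
Pyro-glu-E	nterm:E	H-2 O-1
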