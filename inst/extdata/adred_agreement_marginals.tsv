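comparison	enzyme	n_joint	manual_substrates	automatic_substrates
DRUGBANK	CYP2D6	100	9	12
DRUGBANK	CYP2C19	100	8	11
DRUGBANK	CYP2C9	100	6	17
FDA	CYP2D6	12	3	1
FDA	CYP2C19	12	3	1
FDA	CYP2C9	12	0	0
FLOCKHART	CYP2D6	26	7	6
FLOCKHART	CYP2C19	26	7	6
FLOCKHART	CYP2C9	26	2	5
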