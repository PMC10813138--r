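name	CYP2D6	CYP2C9	CYP2C19	reviewer_1	reviewer_2	consensus
simvastatin	1	0	0	CP	MS	1
escitalopram	1	0	1	CP	MS	1
clopidogrel	0	0	1	CP	PH	1
apixaban	0	1	1	CP	PH	1
tilidine	0	0	1	CP	MS	1
metoprolol	1	0	0	CP	PH	1
omeprazole	0	0	1	CP	MS	1
acetylsalicylic acid	0	0	0	CP	PH	1
ramipril	0	0	0	CP	MS	1
metamizole	0	0	0	CP	PH	1
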