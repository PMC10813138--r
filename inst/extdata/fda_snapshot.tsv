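#policy=LISTED_ONLY
#id=FDA
#version=2023-09-22-transcription
name	atc	CYP2D6	CYP2C9	CYP2C19	note
dextromethorphan	R05DA09	1	0	0	sensitive index substrate
desipramine	N06AA01	1	0	0	sensitive index substrate
omeprazole	A02BC01	0	0	1	sensitive index substrate
simvastatin	C10AA01	0	0	0	listed for CYP3A only
escitalopram	N06AB10	0	0	0	listed outside the CYP2 panel in this transcription
clopidogrel	B01AC04	0	0	0	listed as inhibitor example only
caffeine	N06BC01	0	0	0	CYP1A2 substrate example
celecoxib	M01AH01	0	1	0	moderate sensitivity substrate
tolbutamide	A10BB03	0	1	0	moderate sensitivity substrate
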