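#policy=LISTED_ONLY
#id=FLOCKHART
#version=2023-09-22-transcription
name	atc	CYP2D6	CYP2C9	CYP2C19	note
losartan	C09CA01	0	1	0	listed CYP2C9 substrate
irbesartan	C09CA04	0	1	0	listed CYP2C9 substrate
olodaterol	R03AC19	0	1	0	listed CYP2C9 substrate
clopidogrel	B01AC04	0	1	1	listed CYP2C9 and CYP2C19 substrate
apixaban	B01AF02	0	0	0	listed under CYP3A only
metoprolol	C07AB02	1	0	0	listed CYP2D6 substrate
amitriptyline	N06AA09	1	0	1	listed CYP2D6 and CYP2C19 substrate
omeprazole	A02BC01	0	0	1	listed CYP2C19 substrate
pantoprazole	A02BC02	0	0	1	listed CYP2C19 substrate
simvastatin	C10AA01	0	0	0	listed under CYP3A only
escitalopram	N06AB10	0	0	0	listed under CYP3A only
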