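atc	name
C09AA05	ramipril
C07AB02	metoprolol
C03AA03	hydrochlorothiazide
A02BC02	pantoprazole
A02BC01	omeprazole
B01AC06	acetylsalicylic acid
N02BB02	metamizole
C10AA01	simvastatin
N06AB10	escitalopram
B01AC04	clopidogrel
B01AF02	apixaban
N02AX01	tilidine
C09CA01	losartan
C09CA04	irbesartan
R03AC19	olodaterol
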