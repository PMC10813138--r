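case_id,name,atc
case001,Ramipril 5mg,C09AA05
case001,Hydrochlorothiazid/Ramipril,
case002,Metoprololtartrat,C07AB02
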