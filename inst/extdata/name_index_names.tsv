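name
caffeine
acetaminophen
dapagliflozin
naloxone
valsartan
carvedilol
ondansetron
ibuprofen
dexibuprofen
torasemide
levothyroxine
amlodipine
allopurinol
phenprocoumon
dextromethorphan
desipramine
celecoxib
tolbutamide
amitriptyline
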