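raw	canonical
ass	acetylsalicylic acid
novalgin	metamizole
paracetamol	acetaminophen
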