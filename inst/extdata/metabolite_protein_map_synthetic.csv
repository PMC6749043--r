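metabolite,protein
tyrosine,TH
tyrosine,TYR
methionine,CBS
methionine,CTH
serine,CBS
serine,CTH
Alanine,ALT
Alanine,AGXT2
glutamate,ALT
glutamate,KAT
glutamine,KAT
choline,PLD2
histidine,HDC
glycine,AGXT2
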