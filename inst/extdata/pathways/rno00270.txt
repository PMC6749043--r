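C00073 C00019
C00019 C00021
C00021 C00155
C00155 C00073
C00155 C02291
C02291 C00097
C00065 C02291
C00097 C00022
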