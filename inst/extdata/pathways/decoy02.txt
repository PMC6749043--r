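C00212 C00147
C00147 C00262
C00262 C00385
C00385 C00366
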