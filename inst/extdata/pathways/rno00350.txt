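C00082 C00355
C00355 C03758
C00082 C01179
C01179 C00544
C00544 C00122
C00544 C00164
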