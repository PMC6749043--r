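C00188 C00109
C00109 C00407
C00109 C06010
C00022 C06010
C06010 C00141
C00141 C00183
C00141 C00123
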