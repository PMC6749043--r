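C00251 C00254
C00254 C00166
C00166 C00079
C00254 C01179
C01179 C00082
C00251 C00108
C00108 C00078
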