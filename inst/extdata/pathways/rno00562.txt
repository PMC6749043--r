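C00092 C01177
C01177 C00137
C00137 C01194
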