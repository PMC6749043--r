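C00092 C00345
C00345 C00199
C00199 C00117
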