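C00246 C00232
C00232 C00042
C00042 C00334
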